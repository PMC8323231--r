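#' Extract connected lesion components from a binary mask
#'
#' Labels connected foreground components under 4- or 8-connectivity
#' (default 8: blob-like lesions own their diagonal pixels) by iterative
#' vectorized minimum-label propagation, and returns one instance per
#' component in deterministic row-major order of the bounding-box origin.
#'
#' @param binary_mask Logical or 0/1 numeric matrix.
#' @param connectivity 4 or 8 (default).
#' @return A tibble with one row per component: `id`, `area`,
#'   `centroid_row`/`centroid_col` (arithmetic means of member pixel
#'   coordinates), bounding box `min_row`/`min_col`/`max_row`/`max_col`,
#'   and a `pixels` list-column of (row, col) integer matrices sorted
#'   row-major. An empty mask yields a zero-row tibble.
#' @examples
#' m <- matrix(0, 8, 8); m[2:4, 2:4] <- 1
#' extract_components(m)
#' @export
extract_components <- function(binary_mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  fg <- binary_mask > 0
  H <- nrow(fg); W <- ncol(fg)
  if (!any(fg)) return(empty_component_tibble())
  lab <- matrix(Inf, H, W)
  lab[fg] <- which(fg)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  repeat {
    nb <- matrix(Inf, H, W)
    for (s in shifts) {
      shifted <- matrix(Inf, H, W)
      r_dst <- max(1L, 1L + s[1L]):min(H, H + s[1L])
      c_dst <- max(1L, 1L + s[2L]):min(W, W + s[2L])
      shifted[r_dst, c_dst] <- lab[r_dst - s[1L], c_dst - s[2L]]
      nb <- pmin(nb, shifted)
    }
    new_lab <- lab
    upd <- fg & nb < lab
    if (!any(upd)) break
    new_lab[upd] <- nb[upd]
    lab <- new_lab
  }
  ids <- lab[fg]
  rows <- row(fg)[fg]
  cols <- col(fg)[fg]
  comp <- split(seq_along(ids), ids)
  out <- purrr::map(comp, function(ii) {
    r <- rows[ii]; cc <- cols[ii]
    o <- order(r, cc)
    px <- cbind(row = r[o], col = cc[o])
    tibble::tibble(area = length(ii),
                   centroid_row = mean(r), centroid_col = mean(cc),
                   min_row = min(r), min_col = min(cc),
                   max_row = max(r), max_col = max(cc),
                   pixels = list(px))
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$min_row, .data$min_col)
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1L)
}

empty_component_tibble <- function() {
  tibble::tibble(id = integer(), area = integer(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 min_row = integer(), min_col = integer(),
                 max_row = integer(), max_col = integer(), pixels = list())
}

#' Classify one lesion instance from its T1 ROI
#'
#' Extracts the gamma-transformed T1 ROI at the instance centroid (see
#' [extract_roi()]) and scores it with the secondary network. The class is
#' LACI when the score strictly exceeds `threshold`, FCI otherwise (a tie at
#' exactly the threshold resolves to FCI).
#'
#' @param instance One row of an [extract_components()] tibble (or any list
#'   with `centroid_row`/`centroid_col`).
#' @param t1 T1 intensity matrix.
#' @param secondary A `secondary_net` or `secondary_fit`.
#' @param threshold Decision threshold on P(LACI), default 0.5.
#' @inheritParams extract_roi
#' @return A list with `class` (`"FCI"` or `"LACI"`) and `score` (P(LACI)).
#' @export
classify_instance <- function(instance, t1, secondary, threshold = 0.5,
                              crop_size = 32L, out_size = 64L, gamma = 1.5) {
  net <- if (inherits(secondary, "secondary_fit")) secondary$net else secondary
  roi <- extract_roi(t1, c(instance$centroid_row, instance$centroid_col),
                     crop_size = crop_size, out_size = out_size, gamma = gamma)
  score <- predict_secondary(net, roi)
  list(class = if (score > threshold) "LACI" else "FCI", score = score)
}

#' Correct a binary segmentation into a semantic mask
#'
#' Relabels each instance's pixels with its predicted class (1 = FCI,
#' 2 = LACI). Correction changes classes only, never geometry: the
#' foreground of the result is bit-identical to the input binary mask.
#'
#' @param binary_mask Logical or 0/1 matrix.
#' @param instances An instance tibble covering exactly the mask foreground,
#'   with a `predicted_class` column.
#' @return Integer matrix in \{0, 1, 2\}.
#' @export
correct_segmentation <- function(binary_mask, instances) {
  fg <- binary_mask > 0
  out <- matrix(0L, nrow(fg), ncol(fg))
  if (nrow(instances) == 0L) {
    if (any(fg)) stop("instances do not cover the mask foreground")
    return(out)
  }
  if (!"predicted_class" %in% names(instances) ||
      any(!instances$predicted_class %in% c("FCI", "LACI"))) {
    stop("every instance needs a predicted_class of \"FCI\" or \"LACI\"")
  }
  covered <- matrix(FALSE, nrow(fg), ncol(fg))
  for (i in seq_len(nrow(instances))) {
    px <- instances$pixels[[i]]
    if (any(covered[px]) || any(!fg[px])) {
      stop("instances must partition the mask foreground")
    }
    covered[px] <- TRUE
    out[px] <- if (instances$predicted_class[i] == "LACI") 2L else 1L
  }
  if (!identical(covered, fg)) stop("instances do not cover the mask foreground")
  out
}

#' Run the full segmentation-correction cascade on one slice pair
#'
#' The primary network segments the T2 image (per-pixel argmax; ties resolve
#' to background), connected components become lesion instances, each is
#' classified on the T1 image by the secondary network, and the classes are
#' written back into a semantic mask. Slices with no predicted components
#' return an all-zero mask without invoking the secondary network.
#'
#' @param pair A `slice_pair`.
#' @param primary A trained `primary_fit` (or bare `primary_net`).
#' @param secondary A trained `secondary_fit` (or bare `secondary_net`).
#' @param cls_threshold Decision threshold on P(LACI), default 0.5.
#' @param connectivity Component connectivity, 4 or 8.
#' @param min_lesion_px Drop predicted components smaller than this many
#'   pixels (default 0 = keep all).
#' @return A list with `mask` (integer semantic mask in \{0, 1, 2\}) and
#'   `instances` (component tibble with `predicted_class` and `score`).
#' @export
run_inference <- function(pair, primary, secondary, cls_threshold = 0.5,
                          connectivity = 8L, min_lesion_px = 0L) {
  stopifnot(inherits(pair, "slice_pair"))
  pnet <- if (inherits(primary, "primary_fit")) primary$net else primary
  probs <- predict_primary(pnet, pair$t2)
  pred <- argmax_background_ties(probs)
  binary <- pred > 1L
  inst <- extract_components(binary, connectivity = connectivity)
  if (min_lesion_px > 0L && nrow(inst) > 0L) {
    dropped <- inst[inst$area < min_lesion_px, ]
    for (i in seq_len(nrow(dropped))) binary[dropped$pixels[[i]]] <- FALSE
    inst <- inst[inst$area >= min_lesion_px, ]
  }
  if (nrow(inst) == 0L) {
    return(list(mask = matrix(0L, nrow(binary), ncol(binary)),
                instances = dplyr::mutate(empty_component_tibble(),
                                          predicted_class = character(),
                                          score = numeric())))
  }
  cls <- purrr::map(seq_len(nrow(inst)), function(i) {
    classify_instance(inst[i, ], pair$t1, secondary, threshold = cls_threshold)
  })
  inst$predicted_class <- vapply(cls, `[[`, character(1), "class")
  inst$score <- vapply(cls, `[[`, numeric(1), "score")
  list(mask = correct_segmentation(binary, inst), instances = inst)
}

# channel argmax with ties resolved to the lowest class index (background
# first), giving conservative detection on exact ties.
argmax_background_ties <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1L] * d[2L], d[3L])
  matrix(max.col(m, ties.method = "first"), d[1L], d[2L])
}

# One-stage (task a) semantic inference: 3-class argmax; instances from the
# binary foreground with majority-vote class.
run_inference_onestage <- function(pair, primary, connectivity = 8L) {
  pnet <- if (inherits(primary, "primary_fit")) primary$net else primary
  stopifnot(pnet$spec$n_classes == 3L)
  probs <- predict_primary(pnet, pair$t2)
  pred <- argmax_background_ties(probs) - 1L # 0 = background
  inst <- extract_components(pred > 0L, connectivity = connectivity)
  if (nrow(inst) > 0L) {
    inst$predicted_class <- vapply(seq_len(nrow(inst)), function(i) {
      majority_class(pred, inst$pixels[[i]])
    }, character(1))
    inst$score <- NA_real_
  } else {
    inst$predicted_class <- character()
    inst$score <- numeric()
  }
  list(mask = pred, instances = inst)
}

# majority label over a component's pixels; ties resolve to FCI (label 1)
majority_class <- function(labels, pixels) {
  v <- labels[pixels]
  if (sum(v == 2L) > sum(v == 1L)) "LACI" else "FCI"
}
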