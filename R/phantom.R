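#' Phantom generator configuration
#'
#' Parameters of the seeded phantom that emulates paired T2/T1 FLAIR slices
#' with planted tiny lesions of two classes. On T2 both lesion classes are
#' bright relative to brain tissue; on T1, FCI lesions are isointense with
#' brain (no obvious signal) while LACI lesions are dark. All intensities
#' are normalized to `[0, 1]`.
#'
#' @param image_size Pixels per side (default 128; the clinical analogue is
#'   512, configurable).
#' @param lesion_radius_range Integer interval of lesion disk radii in
#'   pixels; default `c(1, 4)` ("tiny" relative to the image).
#' @param lesion_count_range Integer interval of lesions per lesional slice;
#'   default `c(1, 8)`, matching the strong slice-to-slice variability of
#'   clinical lesion counts.
#' @param class_mix Probability that a lesion is LACI rather than FCI
#'   (default 0.27, echoing the LACI share of lesional images in the
#'   reference cohort: 70 of 261).
#' @param background_level,brain_level Intensity outside/inside the brain
#'   ellipse.
#' @param t2_lesion_level Lesion intensity on T2; must exceed `brain_level`.
#' @param t1_fci_level T1 intensity of FCI lesions; must be within a small
#'   margin of `brain_level` (isointense).
#' @param t1_laci_level T1 intensity of LACI lesions; must be below
#'   `brain_level`.
#' @param noise_sd Standard deviation of additive Gaussian noise (clipped to
#'   `[0, 1]` after addition).
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           lesion_radius_range = c(1L, 4L),
                           lesion_count_range = c(1L, 8L),
                           class_mix = 0.27,
                           background_level = 0.05,
                           brain_level = 0.5,
                           t2_lesion_level = 0.9,
                           t1_fci_level = 0.5,
                           t1_laci_level = 0.15,
                           noise_sd = 0.02,
                           seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              lesion_radius_range = as.integer(lesion_radius_range),
              lesion_count_range = as.integer(lesion_count_range),
              class_mix = class_mix,
              background_level = background_level,
              brain_level = brain_level,
              t2_lesion_level = t2_lesion_level,
              t1_fci_level = t1_fci_level,
              t1_laci_level = t1_laci_level,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  lv <- c(cfg$background_level, cfg$brain_level, cfg$t2_lesion_level,
          cfg$t1_fci_level, cfg$t1_laci_level)
  if (any(lv < 0 | lv > 1)) stop("intensity levels must lie in [0, 1]")
  if (cfg$t1_laci_level >= cfg$brain_level) {
    stop("`t1_laci_level` must be below `brain_level` (LACI is dark on T1)")
  }
  if (cfg$t2_lesion_level <= cfg$brain_level) {
    stop("`t2_lesion_level` must exceed `brain_level` (lesions are bright on T2)")
  }
  margin <- max(0.1, 5 * cfg$noise_sd)
  if (abs(cfg$t1_fci_level - cfg$brain_level) >= margin) {
    stop("`t1_fci_level` must be within ", signif(margin, 3),
         " of `brain_level` (FCI shows no obvious T1 signal)")
  }
  rr <- cfg$lesion_radius_range
  cr <- cfg$lesion_count_range
  if (length(rr) != 2L || any(is.na(rr)) || rr[1L] > rr[2L] || rr[1L] < 1L) {
    stop("`lesion_radius_range` must be a nonempty integer interval >= 1")
  }
  if (length(cr) != 2L || any(is.na(cr)) || cr[1L] > cr[2L] || cr[1L] < 0L) {
    stop("`lesion_count_range` must be a nonempty integer interval >= 0")
  }
  if (cfg$class_mix < 0 || cfg$class_mix > 1) stop("`class_mix` must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (cfg$image_size < 16L) stop("`image_size` must be at least 16")
  invisible(cfg)
}

# brain ellipse membership for all pixels; semi-axes fractions of image size
brain_ellipse <- function(size, shrink_r = 0, shrink_c = 0) {
  ctr <- (size + 1) / 2
  a <- 0.42 * size - shrink_r
  b <- 0.36 * size - shrink_c
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - ctr) / a)^2 + ((cols - ctr) / b)^2 <= 1
}

# uniform integer draw on [lo, hi]; safe when lo == hi (sample() would
# otherwise treat a scalar as 1:n)
sample_int_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

disk_pixels <- function(center, radius, size) {
  r0 <- max(1L, center[1L] - radius)
  r1 <- min(size, center[1L] + radius)
  c0 <- max(1L, center[2L] - radius)
  c1 <- min(size, center[2L] + radius)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
  cbind(row = rows[keep], col = cols[keep])
}

#' Generate one phantom slice pair with ground truth
#'
#' Paints an elliptical "brain" over background, plants `n_lesions`
#' non-overlapping lesion disks (bright on T2; isointense FCI or dark LACI
#' on T1), adds i.i.d. Gaussian noise and clips to `[0, 1]`. The label mask
#' marks exactly the painted pixels (1 = FCI, 2 = LACI) and the instance
#' table agrees with the mask by construction.
#'
#' @param config A [phantom_config()].
#' @param patient_id,slice_id Identifiers stored on the slice pair.
#' @param n_lesions Number of lesions; default draws uniformly from
#'   `config$lesion_count_range`.
#' @param seed Seed for this slice; defaults to `config$seed`.
#' @return A list with `pair` (class `slice_pair`: matrices `t2`, `t1`, ids),
#'   `mask` (integer matrix in \{0, 1, 2\}), and `instances` (tibble with
#'   `class`, centroid, radius, `area`, bounding box and a `pixels`
#'   list-column of (row, col) matrices).
#' @examples
#' s <- generate_slice(phantom_config(image_size = 64, noise_sd = 0), seed = 7)
#' table(s$mask)
#' @export
generate_slice <- function(config, patient_id = "P001", slice_id = "S001",
                           n_lesions = NULL, seed = config$seed) {
  validate_phantom_config(config)
  set.seed(seed)
  size <- config$image_size
  brain <- brain_ellipse(size)
  t2 <- matrix(config$background_level, size, size)
  t2[brain] <- config$brain_level
  t1 <- t2
  mask <- matrix(0L, size, size)
  if (is.null(n_lesions)) {
    n_lesions <- sample_int_range(config$lesion_count_range[1L],
                                  config$lesion_count_range[2L])
  }
  placed <- list()
  instances <- list()
  if (n_lesions > 0L) {
    ctr <- (size + 1) / 2
    for (i in seq_len(n_lesions)) {
      radius <- sample_int_range(config$lesion_radius_range[1L],
                                 config$lesion_radius_range[2L])
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        cand <- c(sample.int(size, 1L), sample.int(size, 1L))
        a <- 0.42 * size - radius - 2
        b <- 0.36 * size - radius - 2
        if (a <= 0 || b <= 0) next
        if (((cand[1L] - ctr) / a)^2 + ((cand[2L] - ctr) / b)^2 > 1) next
        clash <- FALSE
        for (p in placed) {
          if (sqrt(sum((cand - p$center)^2)) <= radius + p$radius + 3) {
            clash <- TRUE
            break
          }
        }
        if (!clash) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", n_lesions, " non-overlapping lesions; ",
             "the configuration is too dense")
      }
      cls <- if (stats::runif(1) < config$class_mix) "LACI" else "FCI"
      px <- disk_pixels(cand, radius, size)
      t2[px] <- config$t2_lesion_level
      t1[px] <- if (cls == "LACI") config$t1_laci_level else config$t1_fci_level
      mask[px] <- if (cls == "LACI") 2L else 1L
      placed[[i]] <- list(center = cand, radius = radius)
      instances[[i]] <- tibble::tibble(
        class = cls,
        centroid_row = mean(px[, "row"]),
        centroid_col = mean(px[, "col"]),
        radius = radius,
        area = nrow(px),
        min_row = min(px[, "row"]), min_col = min(px[, "col"]),
        max_row = max(px[, "row"]), max_col = max(px[, "col"]),
        pixels = list(px))
    }
  }
  if (config$noise_sd > 0) {
    t2 <- t2 + stats::rnorm(length(t2), sd = config$noise_sd)
    t1 <- t1 + stats::rnorm(length(t1), sd = config$noise_sd)
    t2 <- pmin(pmax(t2, 0), 1)
    t1 <- pmin(pmax(t1, 0), 1)
  }
  inst <- if (length(instances)) dplyr::bind_rows(instances) else empty_instances()
  # deterministic row-major ordering by bounding-box origin
  inst <- dplyr::arrange(inst, .data$min_row, .data$min_col)
  list(pair = new_slice_pair(t2, t1, patient_id, slice_id),
       mask = mask,
       instances = inst)
}

new_slice_pair <- function(t2, t1, patient_id, slice_id) {
  if (!identical(dim(t2), dim(t1))) stop("t2 and t1 shapes must match")
  if (any(!is.finite(t2)) || any(!is.finite(t1)) ||
      min(t2, t1) < 0 || max(t2, t1) > 1) {
    stop("slice intensities must be finite and in [0, 1]")
  }
  structure(list(t2 = t2, t1 = t1, patient_id = patient_id,
                 slice_id = slice_id),
            class = "slice_pair")
}

empty_instances <- function() {
  tibble::tibble(class = character(), centroid_row = numeric(),
                 centroid_col = numeric(), radius = integer(),
                 area = integer(), min_row = integer(), min_col = integer(),
                 max_row = integer(), max_col = integer(), pixels = list())
}

#' Generate a phantom dataset of patients and slices
#'
#' Draws per-patient health status (healthy patients carry no lesions) and
#' generates `slices_per_patient` seeded slices per patient. The default
#' healthy fraction (37/135) mirrors the reference cohort proportions of
#' healthy to lesional patients.
#'
#' @param config A [phantom_config()].
#' @param n_patients Number of patients (>= 5 so five-fold patient-level CV
#'   is possible).
#' @param slices_per_patient Slices generated per patient.
#' @param healthy_fraction Probability a patient is healthy.
#' @param seed Root seed; per-slice seeds are derived from it.
#' @return A tibble with one row per slice: `patient_id`, `slice_id`,
#'   `healthy`, list-columns `t2`, `t1`, `mask`, `instances`, and
#'   `n_lesions`.
#' @examples
#' ds <- generate_dataset(phantom_config(image_size = 64), n_patients = 5,
#'                        slices_per_patient = 2, seed = 1)
#' dplyr::count(ds, healthy)
#' @export
generate_dataset <- function(config, n_patients = 25L, slices_per_patient = 3L,
                             healthy_fraction = 37 / 135, seed = config$seed) {
  validate_phantom_config(config)
  if (n_patients < 5L) {
    stop("`n_patients` must be at least 5 (five-fold cross-validation)")
  }
  set.seed(seed)
  healthy <- stats::runif(n_patients) < healthy_fraction
  slice_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_patients * slices_per_patient),
                        n_patients, slices_per_patient)
  rows <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (s in seq_len(slices_per_patient)) {
      sid <- sprintf("%s_S%02d", pid, s)
      sl <- generate_slice(config, patient_id = pid, slice_id = sid,
                           n_lesions = if (healthy[p]) 0L else NULL,
                           seed = slice_seeds[p, s])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, slice_id = sid, healthy = healthy[p],
        t2 = list(sl$pair$t2), t1 = list(sl$pair$t1), mask = list(sl$mask),
        instances = list(sl$instances), n_lesions = nrow(sl$instances))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.slice_pair <- function(x, ...) {
  cat("Slice pair", x$slice_id, "of patient", x$patient_id, "-",
      paste(dim(x$t2), collapse = "x"), "T2/T1 FLAIR\n")
  invisible(x)
}
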