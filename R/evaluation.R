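#' Evaluation configuration
#'
#' @param iou_threshold Strict IoU threshold for a true-positive detection:
#'   a predicted instance counts only when IoU is strictly greater than this
#'   (default 0.6).
#' @param n_folds Number of cross-validation folds (default 5).
#' @param split_unit `"patient"` (default; a patient never straddles folds)
#'   or `"slice"`.
#' @param seed Seed for the fold shuffle.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(iou_threshold = 0.6, n_folds = 5L,
                        split_unit = c("patient", "slice"), seed = 1L) {
  split_unit <- match.arg(split_unit)
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop("`iou_threshold` must be in (0, 1]")
  }
  if (n_folds < 2L) stop("`n_folds` must be at least 2")
  structure(list(iou_threshold = iou_threshold, n_folds = as.integer(n_folds),
                 split_unit = split_unit, seed = as.integer(seed)),
            class = "eval_config")
}

#' Dice coefficient between two binary masks
#'
#' `2|P intersect T| / (|P| + |T|)`; when both masks are empty the slice is
#' perfectly segmented and the value is 1 by convention.
#'
#' @param pred_binary,true_binary Same-shape logical or 0/1 matrices.
#' @return A value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred_binary, true_binary) {
  if (!identical(dim(pred_binary), dim(true_binary))) {
    stop("mask shapes differ")
  }
  p <- pred_binary > 0
  t <- true_binary > 0
  denom <- sum(p) + sum(t)
  if (denom == 0L) return(1)
  2 * sum(p & t) / denom
}

pixel_key <- function(px) px[, 1L] * 1e6 + px[, 2L]

instance_pixels <- function(x) {
  if (is.matrix(x)) return(x)
  px <- x$pixels
  if (is.list(px) && !is.matrix(px)) px <- px[[1L]]
  px
}

#' Intersection over union of two lesion instances
#'
#' @param a,b Instance rows (from [extract_components()]) or raw (row, col)
#'   pixel matrices.
#' @param on `"pixels"` (default) computes IoU on the exact pixel sets;
#'   `"bbox"` on the axis-aligned bounding boxes.
#' @return `|A intersect B| / |A union B|` in `[0, 1]`.
#' @export
instance_iou <- function(a, b, on = c("pixels", "bbox")) {
  on <- match.arg(on)
  if (on == "bbox") return(bbox_iou(instance_bbox(a), instance_bbox(b)))
  ka <- pixel_key(instance_pixels(a))
  kb <- pixel_key(instance_pixels(b))
  inter <- length(intersect(ka, kb))
  inter / (length(ka) + length(kb) - inter)
}

instance_bbox <- function(x) {
  if (is.matrix(x)) {
    c(min(x[, 1L]), min(x[, 2L]), max(x[, 1L]), max(x[, 2L]))
  } else {
    c(x$min_row, x$min_col, x$max_row, x$max_col)
  }
}

bbox_iou <- function(a, b) {
  ir <- min(a[3L], b[3L]) - max(a[1L], b[1L]) + 1L
  ic <- min(a[4L], b[4L]) - max(a[2L], b[2L]) + 1L
  if (ir <= 0L || ic <= 0L) return(0)
  inter <- ir * ic
  area <- function(z) (z[3L] - z[1L] + 1L) * (z[4L] - z[2L] + 1L)
  inter / (area(a) + area(b) - inter)
}

#' Match predicted to true lesion instances
#'
#' Greedy one-to-one matching in descending IoU order; a pair matches only
#' when its IoU is strictly greater than `iou_threshold`. Unmatched
#' predictions are false positives, unmatched truths false negatives. Ties
#' are broken by bounding-box position so the result does not depend on
#' input ordering.
#'
#' @param pred_instances,true_instances Instance tibbles (see
#'   [extract_components()]); class columns (`predicted_class`, `class`)
#'   are carried into the matches when present.
#' @param iou_threshold Strict threshold, default 0.6.
#' @param on Match on exact `"pixels"` (default) or `"bbox"` rectangles.
#' @return A list with `matches` (tibble: `pred_id`, `true_id`, `iou`, and
#'   classes when available), `false_positives` and `false_negatives`
#'   (integer row indices), and counts `tp`, `fp`, `fn`.
#' @export
match_detections <- function(pred_instances, true_instances,
                             iou_threshold = 0.6, on = c("pixels", "bbox")) {
  on <- match.arg(on)
  np <- nrow(pred_instances)
  nt <- nrow(true_instances)
  pairs <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      iou <- instance_iou(pred_instances[i, ], true_instances[j, ], on = on)
      if (iou > iou_threshold) {
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          pred_id = i, true_id = j, iou = iou,
          p_row = pred_instances$min_row[i], p_col = pred_instances$min_col[i],
          t_row = true_instances$min_row[j], t_col = true_instances$min_col[j])
      }
    }
  }
  matches <- tibble::tibble(pred_id = integer(), true_id = integer(),
                            iou = numeric())
  if (length(pairs)) {
    cand <- dplyr::arrange(dplyr::bind_rows(pairs),
                           dplyr::desc(.data$iou), .data$p_row, .data$p_col,
                           .data$t_row, .data$t_col)
    used_p <- logical(np)
    used_t <- logical(nt)
    keep <- list()
    for (r in seq_len(nrow(cand))) {
      i <- cand$pred_id[r]; j <- cand$true_id[r]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE
        used_t[j] <- TRUE
        keep[[length(keep) + 1L]] <- cand[r, c("pred_id", "true_id", "iou")]
      }
    }
    matches <- dplyr::bind_rows(keep)
  }
  if ("predicted_class" %in% names(pred_instances) && nrow(matches) > 0L) {
    matches$pred_class <- pred_instances$predicted_class[matches$pred_id]
  }
  if ("class" %in% names(true_instances) && nrow(matches) > 0L) {
    matches$true_class <- true_instances$class[matches$true_id]
  }
  list(matches = matches,
       false_positives = setdiff(seq_len(np), matches$pred_id),
       false_negatives = setdiff(seq_len(nt), matches$true_id),
       tp = nrow(matches),
       fp = np - nrow(matches),
       fn = nt - nrow(matches))
}

#' Detection precision
#'
#' Ratio of true-positive detections to all predicted positives,
#' `TP / (TP + FP)`. With no predicted positives at all (`TP = FP = 0`) the
#' quantity is undefined and `NA` is returned; undefined folds are excluded
#' from cross-validation means.
#'
#' @param matches True-positive count, or the result of [match_detections()].
#' @param false_positives False-positive count (ignored when `matches` is a
#'   match result).
#' @return Precision in `[0, 1]`, or `NA` when undefined.
#' @export
detection_precision <- function(matches, false_positives = NULL) {
  if (is.list(matches) && !is.null(matches$tp)) {
    tp <- matches$tp
    fp <- matches$fp
  } else {
    tp <- matches
    fp <- false_positives
  }
  if (tp < 0 || fp < 0) stop("counts must be nonnegative")
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' Classification precision over matched instances
#'
#' Fraction of true-positive (matched) instances whose predicted class
#' equals the true class.
#'
#' @param matched_pairs The `matches` tibble of [match_detections()] (or a
#'   match result), with `pred_class` and `true_class` columns.
#' @return Fraction in `[0, 1]`, or `NA` when there are no matches.
#' @export
classification_precision <- function(matched_pairs) {
  if (!is.data.frame(matched_pairs) && is.list(matched_pairs) &&
      "matches" %in% names(matched_pairs)) {
    matched_pairs <- matched_pairs$matches
  }
  if (nrow(matched_pairs) == 0L) return(NA_real_)
  if (!all(c("pred_class", "true_class") %in% names(matched_pairs))) {
    stop("matched pairs must carry `pred_class` and `true_class`")
  }
  mean(matched_pairs$pred_class == matched_pairs$true_class)
}

# fold assignment: shuffle units, deal round-robin so sizes differ by <= 1
assign_folds <- function(units, n_folds, seed) {
  set.seed(seed)
  shuffled <- sample(units)
  fold <- rep(seq_len(n_folds), length.out = length(units))
  stats::setNames(fold, shuffled)
}

# evaluate one trained model over the slices of a test fold
evaluate_fold <- function(model, test_tbl, eval_cfg, connectivity = 8L) {
  inter <- 0; psum <- 0; tsum <- 0
  tp <- 0L; fp <- 0L; fn <- 0L; cls_ok <- 0L
  for (i in seq_len(nrow(test_tbl))) {
    row <- test_tbl[i, ]
    pred <- model$predict(row)
    truth_mask <- row$mask[[1L]]
    true_inst <- extract_components(truth_mask > 0L, connectivity)
    if (nrow(true_inst) > 0L) {
      true_inst$class <- vapply(seq_len(nrow(true_inst)), function(k) {
        majority_class(truth_mask, true_inst$pixels[[k]])
      }, character(1))
    } else {
      true_inst$class <- character()
    }
    pb <- pred$mask > 0L
    tb <- truth_mask > 0L
    inter <- inter + sum(pb & tb)
    psum <- psum + sum(pb)
    tsum <- tsum + sum(tb)
    m <- match_detections(pred$instances, true_inst, eval_cfg$iou_threshold)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (m$tp > 0L && "pred_class" %in% names(m$matches)) {
      cls_ok <- cls_ok + sum(m$matches$pred_class == m$matches$true_class)
    }
  }
  tibble::tibble(
    dice = if (psum + tsum == 0) 1 else 2 * inter / (psum + tsum),
    detection_precision = detection_precision(tp, fp),
    classification_precision = if (tp > 0L) cls_ok / tp else NA_real_,
    tp = tp, fp = fp, fn = fn, n_slices = nrow(test_tbl))
}

#' Patient-level k-fold cross-validation
#'
#' Partitions the split units (patients by default, so no patient's slices
#' leak between training and testing) into `n_folds` folds of sizes
#' differing by at most one, trains a fresh model on each training set and
#' evaluates it on the held-out slices. Each slice is tested exactly once.
#' Fold metrics: Dice over the fold's pooled pixels, detection precision
#' `TP/(TP+FP)` and classification precision over matched instances at the
#' configured IoU threshold. Undefined (no-positive) fold precisions are
#' excluded from the mean.
#'
#' @param dataset A dataset tibble (see [generate_dataset()]).
#' @param train_fn `function(train_tbl, seed)` returning a model with a
#'   `$predict(row)` method, e.g. from [cascade_trainer()].
#' @param eval_cfg An [eval_config()].
#' @return An object of class `cv_result`: `folds` (per-fold tibble) and
#'   `summary` (fold means). Use [tidy()]/[glance()]/`autoplot()`.
#' @export
five_fold_cv <- function(dataset, train_fn, eval_cfg = eval_config()) {
  stopifnot(inherits(eval_cfg, "eval_config"))
  units <- if (eval_cfg$split_unit == "patient") {
    unique(dataset$patient_id)
  } else {
    dataset$slice_id
  }
  if (length(units) < eval_cfg$n_folds) {
    stop("fewer split units than folds")
  }
  folds <- assign_folds(units, eval_cfg$n_folds, eval_cfg$seed)
  key <- if (eval_cfg$split_unit == "patient") dataset$patient_id else dataset$slice_id
  fold_of_slice <- unname(folds[key])
  rows <- list()
  for (f in seq_len(eval_cfg$n_folds)) {
    train_tbl <- dataset[fold_of_slice != f, ]
    test_tbl <- dataset[fold_of_slice == f, ]
    model <- train_fn(train_tbl, seed = eval_cfg$seed * 1000L + f)
    rows[[f]] <- dplyr::mutate(
      evaluate_fold(model, test_tbl, eval_cfg), fold = f, .before = 1L)
  }
  folds_tbl <- dplyr::bind_rows(rows)
  structure(list(
    folds = folds_tbl,
    summary = tibble::tibble(
      dice = mean(folds_tbl$dice),
      detection_precision = mean(folds_tbl$detection_precision, na.rm = TRUE),
      classification_precision = mean(folds_tbl$classification_precision,
                                      na.rm = TRUE)),
    eval_cfg = eval_cfg),
    class = "cv_result")
}

#' Trainer factory for the two-stage cascade
#'
#' Returns a `train_fn` for [five_fold_cv()] that trains the primary
#' segmentation network (binary, task "b") and the secondary correction
#' network on a training fold, then predicts through [run_inference()].
#' Secondary-network training ROIs are taken at ground-truth component
#' centroids by default (`roi_source = "truth"`); `"predicted"` uses the
#' trained primary network's components instead.
#'
#' @param primary_spec,secondary_spec Network specifications.
#' @param cfg A [train_config()] (its seed is overridden per fold).
#' @param oversample Use the two-phase oversampling schedule (default TRUE);
#'   otherwise plain single-phase training with the same phase-2 budget.
#' @param augment Add rotated copies of lesion-rich training slices
#'   (default FALSE). Applied inside the training fold only, never to test
#'   slices.
#' @param oversample_threshold Lesion count defining "lesion-rich"
#'   (default 5).
#' @param class_weights Optional per-class segmentation loss weights.
#' @param roi_source `"truth"` or `"predicted"` secondary training ROIs.
#' @param secondary_epochs,secondary_batch Training budget of the secondary
#'   network (it sees far fewer samples per epoch than the primary, so it
#'   gets its own epoch count; defaults 15 epochs at batch size 2).
#' @param secondary_eta RMSProp learning rate for the secondary network
#'   (default 0.003). Unlike the primary, the secondary has no batch
#'   normalization, and the base rate of 0.01 can drive its ReLU stack into
#'   a dead state from some initializations.
#' @param eta RMSProp base learning rate for both networks.
#' @param connectivity Component connectivity at inference.
#' @return `function(train_tbl, seed)` -> model with `$predict`,
#'   `$primary`, `$secondary`.
#' @export
cascade_trainer <- function(primary_spec, secondary_spec, cfg,
                            oversample = TRUE, augment = FALSE,
                            oversample_threshold = 5L, class_weights = NULL,
                            roi_source = c("truth", "predicted"),
                            secondary_epochs = 15L, secondary_batch = 2L,
                            secondary_eta = 0.003,
                            eta = 0.01, connectivity = 8L) {
  roi_source <- match.arg(roi_source)
  force(primary_spec); force(secondary_spec); force(cfg)
  function(train_tbl, seed) {
    cfg$seed <- as.integer(seed)
    if (augment) train_tbl <- augment_lesion_rich(train_tbl,
                                                  oversample_threshold, seed)
    if (oversample) {
      sched <- build_oversample_schedule(train_tbl$n_lesions,
                                         oversample_threshold)
    } else {
      sched <- single_phase_schedule(nrow(train_tbl))
      cfg$epochs_phase1 <- 0L
    }
    pfit <- train_primary(train_tbl, sched, primary_spec, cfg,
                          class_weights = class_weights, eta = eta)
    rois <- collect_training_rois(train_tbl, roi_source, pfit, connectivity)
    scfg <- train_config(epochs_phase1 = 0L, epochs_phase2 = secondary_epochs,
                         batch_size = secondary_batch,
                         convergence_patience = cfg$convergence_patience,
                         seed = (cfg$seed + 500009L) %% 2000000000L)
    sfit <- train_secondary(rois, secondary_spec, scfg, eta = secondary_eta)
    model <- list(primary = pfit, secondary = sfit)
    model$predict <- function(row) {
      run_inference(new_slice_pair(row$t2[[1L]], row$t1[[1L]],
                                   row$patient_id, row$slice_id),
                    pfit, sfit, connectivity = connectivity)
    }
    model
  }
}

#' Trainer factory for the one-stage (task "a") baseline
#'
#' Trains a single three-class primary network that segments background,
#' FCI and LACI directly; instance classes come from the majority predicted
#' label inside each component.
#'
#' @inheritParams cascade_trainer
#' @param primary_spec A [primary_net_spec()] with `n_classes = 3`.
#' @return `function(train_tbl, seed)` -> model with `$predict`.
#' @export
one_stage_trainer <- function(primary_spec, cfg, oversample = TRUE,
                              augment = FALSE, oversample_threshold = 5L,
                              class_weights = NULL, eta = 0.01,
                              connectivity = 8L) {
  stopifnot(primary_spec$n_classes == 3L)
  function(train_tbl, seed) {
    cfg$seed <- as.integer(seed)
    if (augment) train_tbl <- augment_lesion_rich(train_tbl,
                                                  oversample_threshold, seed)
    if (oversample) {
      sched <- build_oversample_schedule(train_tbl$n_lesions,
                                         oversample_threshold)
    } else {
      sched <- single_phase_schedule(nrow(train_tbl))
      cfg$epochs_phase1 <- 0L
    }
    pfit <- train_primary(train_tbl, sched, primary_spec, cfg,
                          class_weights = class_weights, eta = eta)
    model <- list(primary = pfit)
    model$predict <- function(row) {
      run_inference_onestage(
        new_slice_pair(row$t2[[1L]], row$t1[[1L]],
                       row$patient_id, row$slice_id),
        pfit, connectivity = connectivity)
    }
    model
  }
}

#' Trainer factory for the binary primary network alone
#'
#' Detection-only baseline (task "b" without the correction stage): the
#' primary network segments lesion/background and components are reported
#' without classes.
#'
#' @inheritParams cascade_trainer
#' @return `function(train_tbl, seed)` -> model with `$predict`.
#' @export
primary_only_trainer <- function(primary_spec, cfg, oversample = TRUE,
                                 augment = FALSE, oversample_threshold = 5L,
                                 class_weights = NULL, eta = 0.01,
                                 connectivity = 8L) {
  stopifnot(primary_spec$n_classes == 2L)
  function(train_tbl, seed) {
    cfg$seed <- as.integer(seed)
    if (augment) train_tbl <- augment_lesion_rich(train_tbl,
                                                  oversample_threshold, seed)
    if (oversample) {
      sched <- build_oversample_schedule(train_tbl$n_lesions,
                                         oversample_threshold)
    } else {
      sched <- single_phase_schedule(nrow(train_tbl))
      cfg$epochs_phase1 <- 0L
    }
    pfit <- train_primary(train_tbl, sched, primary_spec, cfg,
                          class_weights = class_weights, eta = eta)
    model <- list(primary = pfit)
    model$predict <- function(row) {
      probs <- predict_primary(pfit$net, row$t2[[1L]])
      binary <- argmax_background_ties(probs) > 1L
      inst <- extract_components(binary, connectivity)
      mask <- matrix(0L, nrow(binary), ncol(binary))
      mask[binary] <- 1L
      list(mask = mask, instances = inst)
    }
    model
  }
}

# add one rotated copy of each lesion-rich training slice (angle drawn from
# the permitted 5-10 degree bands, sign random), seeded.
augment_lesion_rich <- function(train_tbl, threshold, seed) {
  set.seed(seed + 7L)
  rich <- which(train_tbl$n_lesions > threshold)
  extra <- list()
  for (i in rich) {
    ang <- stats::runif(1, 5, 10) * sample(c(-1, 1), 1)
    pair <- new_slice_pair(train_tbl$t2[[i]], train_tbl$t1[[i]],
                           train_tbl$patient_id[i], train_tbl$slice_id[i])
    rot <- augment_rotations(pair, train_tbl$mask[[i]], ang)[[1L]]
    extra[[length(extra) + 1L]] <- tibble::tibble(
      patient_id = train_tbl$patient_id[i],
      slice_id = rot$pair$slice_id,
      healthy = FALSE,
      t2 = list(rot$pair$t2), t1 = list(rot$pair$t1), mask = list(rot$mask),
      instances = list(extract_components(rot$mask > 0L)),
      n_lesions = train_tbl$n_lesions[i])
  }
  dplyr::bind_rows(train_tbl, extra)
}

# ground-truth or predicted-centroid ROIs with true classes for the
# secondary network
collect_training_rois <- function(train_tbl, roi_source, pfit, connectivity) {
  rois <- list()
  for (i in seq_len(nrow(train_tbl))) {
    mask <- train_tbl$mask[[i]]
    t1 <- train_tbl$t1[[i]]
    inst <- if (roi_source == "truth") {
      extract_components(mask > 0L, connectivity)
    } else {
      probs <- predict_primary(pfit$net, train_tbl$t2[[i]])
      extract_components(argmax_background_ties(probs) > 1L, connectivity)
    }
    for (k in seq_len(nrow(inst))) {
      cls <- majority_class(mask, inst$pixels[[k]])
      if (roi_source == "predicted" && !any(mask[inst$pixels[[k]]] > 0L)) next
      rois[[length(rois) + 1L]] <- extract_roi(
        t1, c(inst$centroid_row[k], inst$centroid_col[k]),
        slice_id = train_tbl$slice_id[i], true_class = cls)
    }
  }
  rois
}

#' Run the ablation table
#'
#' Evaluates a set of method variants on the same dataset with identical
#' fold assignments, mirroring the published ablation axes: one-stage
#' (task "a", 3-class) vs two-stage (task "b" + correction), with and
#' without rotation augmentation and the oversampling schedule.
#'
#' @param dataset A dataset tibble.
#' @param variants Character vector of variant names; see
#'   [ablation_variants()]. An empty vector yields an empty table.
#' @param primary_spec A binary [primary_net_spec()]; the task-a variants
#'   reuse it with `n_classes = 3`.
#' @param secondary_spec A [secondary_net_spec()].
#' @param cfg A [train_config()].
#' @param eval_cfg An [eval_config()].
#' @param ... Passed to the trainer factories (e.g. `eta`,
#'   `oversample_threshold`).
#' @return A tibble with one row per variant: the switches and the
#'   fold-mean `dice`, `detection_precision`, `classification_precision`,
#'   plus a `cv` list-column of full `cv_result` objects.
#' @export
run_ablation <- function(dataset, variants, primary_spec, secondary_spec,
                         cfg, eval_cfg = eval_config(), ...) {
  known <- ablation_variants()
  bad <- setdiff(variants, known$variant)
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (v in variants) {
    ax <- known[known$variant == v, ]
    train_fn <- if (ax$two_stage) {
      cascade_trainer(primary_spec, secondary_spec, cfg,
                      oversample = ax$oversample, augment = ax$augment, ...)
    } else if (ax$task == "a") {
      spec3 <- primary_net_spec(primary_spec$depth, primary_spec$base_channels,
                                3L, primary_spec$input_size)
      one_stage_trainer(spec3, cfg, oversample = ax$oversample,
                        augment = ax$augment, ...)
    } else {
      # task b primary alone: detection only, no classification stage
      primary_only_trainer(primary_spec, cfg, oversample = ax$oversample,
                           augment = ax$augment, ...)
    }
    cv <- five_fold_cv(dataset, train_fn, eval_cfg)
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      tibble::tibble(variant = v, task = ax$task, two_stage = ax$two_stage,
                     augment = ax$augment, oversample = ax$oversample),
      dice = cv$summary$dice,
      detection_precision = cv$summary$detection_precision,
      classification_precision = if (ax$two_stage || ax$task == "a")
        cv$summary$classification_precision else NA_real_,
      cv = list(cv))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(variant = character(), task = character(),
                          two_stage = logical(), augment = logical(),
                          oversample = logical(), dice = numeric(),
                          detection_precision = numeric(),
                          classification_precision = numeric(),
                          cv = list()))
  }
  dplyr::bind_rows(rows)
}

#' Supported ablation variants
#'
#' @return A tibble of the recognized variant names and their switches
#'   (task a/b, one- vs two-stage, rotation augmentation, oversampling).
#' @export
ablation_variants <- function() {
  tibble::tribble(
    ~variant, ~task, ~two_stage, ~augment, ~oversample,
    "primary_a", "a", FALSE, FALSE, FALSE,
    "primary_b", "b", FALSE, FALSE, FALSE,
    "primary_a_aug", "a", FALSE, TRUE, FALSE,
    "primary_b_aug", "b", FALSE, TRUE, FALSE,
    "primary_a_oversample", "a", FALSE, FALSE, TRUE,
    "primary_b_oversample", "b", FALSE, FALSE, TRUE,
    "two_stage", "b", TRUE, FALSE, FALSE,
    "two_stage_aug", "b", TRUE, TRUE, FALSE,
    "two_stage_oversample", "b", TRUE, FALSE, TRUE,
    "proposed", "b", TRUE, TRUE, TRUE)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation over", nrow(x$folds), "folds\n")
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold metrics of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold tibble (fold, dice, precisions, counts).
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble of fold-mean dice, detection precision and
#'   classification precision.
#' @export
glance.cv_result <- function(x, ...) x$summary
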