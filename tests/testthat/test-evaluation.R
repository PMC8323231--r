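test_that("dice coefficient matches hand counts and conventions", {
  a <- matrix(0, 6, 6); a[2:3, 2:3] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(dice_coefficient(a, b), 0)
  # |P| = 4, |T| = 4, overlap 2 -> 0.5
  c1 <- matrix(0, 6, 6); c1[2:3, 2:3] <- 1
  c2 <- matrix(0, 6, 6); c2[3:4, 2:3] <- 1
  expect_equal(dice_coefficient(c1, c2), 0.5)
  expect_equal(dice_coefficient(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0, 5, 5)), "shapes")
})

test_that("dice equals 2*IoU/(1+IoU) and is symmetric", {
  set.seed(20)
  for (i in 1:50) {
    a <- random_small_mask(8, 8, 0.4)
    b <- random_small_mask(8, 8, 0.4)
    d <- dice_coefficient(a, b)
    expect_equal(d, dice_coefficient(b, a))
    inter <- sum(a & b)
    uni <- sum(a | b)
    if (uni > 0) {
      iou <- inter / uni
      expect_equal(d, 2 * iou / (1 + iou))
    }
  }
})

test_that("instance IoU matches set enumeration", {
  sq <- function(r0, c0) {
    cbind(row = rep(r0:(r0 + 1), 2), col = rep(c0:(c0 + 1), each = 2))
  }
  expect_equal(instance_iou(sq(2, 2), sq(2, 2)), 1)
  expect_equal(instance_iou(sq(2, 2), sq(10, 10)), 0)
  # 2x2 squares offset by one column: 2 shared of 6 total
  expect_equal(instance_iou(sq(2, 2), sq(2, 3)), 1 / 3)
})

test_that("matching is strict at the IoU threshold", {
  m1 <- matrix(0, 10, 10); m1[2:6, 2:3] <- 1       # 10 px
  m2 <- matrix(0, 10, 10); m2[2:7, 2:3] <- 1       # 12 px, overlap 10
  # IoU = 10/12 > 0.6 matches
  r <- match_detections(extract_components(m1), extract_components(m2), 0.6)
  expect_identical(r$tp, 1L)
  # construct IoU exactly 0.6: |A|=3, |B|=5 overlap 3 -> 3/5
  a <- matrix(0, 10, 10); a[2:4, 2] <- 1
  b <- matrix(0, 10, 10); b[2:6, 2] <- 1
  expect_equal(instance_iou(extract_components(a)[1, ], extract_components(b)[1, ]), 0.6)
  r2 <- match_detections(extract_components(a), extract_components(b), 0.6)
  expect_identical(r2$tp, 0L) # strictly greater than, not equal
  expect_identical(r2$fp, 1L)
  expect_identical(r2$fn, 1L)
})

test_that("matching is one-to-one, order-invariant and optimal for small sets", {
  set.seed(21)
  for (rep in 1:60) {
    # random instance sets from two random masks
    pm <- random_small_mask(12, 12, 0.35)
    tm <- random_small_mask(12, 12, 0.35)
    pred <- extract_components(pm)
    truth <- extract_components(tm)
    if (nrow(pred) > 5 || nrow(truth) > 5) next
    thr <- sample(c(0.2, 0.4, 0.6), 1)
    r <- match_detections(pred, truth, thr)
    # one-to-one
    expect_identical(anyDuplicated(r$matches$pred_id), 0L)
    expect_identical(anyDuplicated(r$matches$true_id), 0L)
    # greedy count equals exhaustive optimum on small sets
    iou_mat <- matrix(0, nrow(pred), nrow(truth))
    for (i in seq_len(nrow(pred))) {
      for (j in seq_len(nrow(truth))) {
        iou_mat[i, j] <- instance_iou(pred[i, ], truth[j, ])
      }
    }
    expect_identical(r$tp, as.integer(best_assignment_count(iou_mat, thr)))
    # order invariance
    if (nrow(pred) > 1) {
      perm <- sample(nrow(pred))
      r2 <- match_detections(pred[perm, ], truth, thr)
      expect_identical(r2$tp, r$tp)
      expect_identical(sort(perm[r2$matches$pred_id]), sort(r$matches$pred_id))
    }
  }
})

test_that("two predictions over one truth yield one match and one FP", {
  truth <- matrix(0, 10, 10); truth[2:5, 2:5] <- 1
  pred <- matrix(0, 10, 10)
  pred[2:5, 2:5] <- 1   # perfect copy
  pred[8:9, 8:9] <- 1   # spurious
  r <- match_detections(extract_components(pred), extract_components(truth), 0.6)
  expect_identical(r$tp, 1L)
  expect_identical(r$fp, 1L)
  expect_identical(r$fn, 0L)
})

test_that("precision conventions follow the definitions", {
  expect_equal(detection_precision(3, 1), 0.75)
  expect_identical(detection_precision(0, 0), NA_real_)
  expect_equal(detection_precision(5, 0), 1)
  expect_error(detection_precision(-1, 2), "nonnegative")
  pairs <- tibble::tibble(pred_class = c(rep("FCI", 10), rep("LACI", 4)),
                          true_class = c(rep("FCI", 10), rep("LACI", 3), "FCI"))
  expect_equal(classification_precision(pairs), 13 / 14)
  expect_equal(classification_precision(pairs[1:3, ]), 1)
  expect_identical(classification_precision(pairs[0, ]), NA_real_)
})

test_that("cross-validation folds partition patients reproducibly", {
  cfg <- phantom_config(image_size = 32, lesion_count_range = c(1L, 2L),
                        lesion_radius_range = c(1L, 2L))
  ds <- generate_dataset(cfg, n_patients = 10, slices_per_patient = 2, seed = 4)
  ecfg <- eval_config(n_folds = 5, seed = 42)
  folds <- lesioncorrect:::assign_folds(unique(ds$patient_id), 5, 42)
  expect_identical(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 2))
  folds2 <- lesioncorrect:::assign_folds(unique(ds$patient_id), 5, 42)
  expect_identical(folds, folds2)
  # constant-prediction model: every slice tested exactly once
  tested <- character(0)
  stub_fn <- function(train_tbl, seed) {
    list(predict = function(row) {
      tested <<- c(tested, row$slice_id)
      list(mask = matrix(0L, 32, 32),
           instances = lesioncorrect:::empty_component_tibble())
    })
  }
  cv <- five_fold_cv(ds, stub_fn, ecfg)
  expect_identical(sort(tested), sort(ds$slice_id))
  expect_identical(nrow(cv$folds), 5L)
  # all-background predictions: detection precision undefined in every fold
  expect_true(all(is.na(cv$folds$detection_precision)))
  expect_error(five_fold_cv(ds[1:8, ], stub_fn, ecfg), "fewer split units")
})

test_that("a perfect-oracle model scores 1 on every metric", {
  cfg <- tiny_phantom_config(image_size = 32, lesion_count_range = c(1L, 3L),
                             lesion_radius_range = c(1L, 2L))
  ds <- generate_dataset(cfg, n_patients = 5, slices_per_patient = 2, seed = 6)
  oracle_fn <- function(train_tbl, seed) {
    list(predict = function(row) {
      mask <- row$mask[[1]]
      inst <- extract_components(mask > 0)
      if (nrow(inst) > 0) {
        inst$predicted_class <- vapply(seq_len(nrow(inst)), function(k) {
          lesioncorrect:::majority_class(mask, inst$pixels[[k]])
        }, character(1))
      } else {
        inst$predicted_class <- character()
      }
      list(mask = mask, instances = inst)
    })
  }
  cv <- five_fold_cv(ds, oracle_fn, eval_config(seed = 9))
  expect_equal(cv$summary$dice, 1)
  expect_equal(cv$summary$detection_precision, 1)
  expect_equal(cv$summary$classification_precision, 1)
  # fold means are arithmetic means of defined folds
  expect_equal(cv$summary$dice, mean(cv$folds$dice))
  expect_identical(nrow(glance(cv)), 1L)
  expect_identical(tidy(cv), cv$folds)
})

test_that("the fold mean of mixed per-fold metrics is arithmetic", {
  vals <- c(1, 1, 1, 1, 0)
  expect_equal(mean(vals), 0.8)
})

test_that("ablation runner validates variants and returns one row each", {
  expect_error(run_ablation(tibble::tibble(), "nope",
                            primary_net_spec(2, 2, 2, 32),
                            secondary_net_spec(base_channels = 2),
                            train_config()),
               "unknown variant")
  empty <- run_ablation(tibble::tibble(), character(0),
                        primary_net_spec(2, 2, 2, 32),
                        secondary_net_spec(base_channels = 2),
                        train_config())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("variant", "dice", "detection_precision",
                    "classification_precision") %in% names(empty)))
  expect_identical(nrow(ablation_variants()), 10L)
})

test_that("fold-internal augmentation adds valid rotated copies of rich slices", {
  ds <- generate_dataset(
    phantom_config(image_size = 64, lesion_count_range = c(4L, 8L)),
    n_patients = 5, slices_per_patient = 1, seed = 3)
  aug <- lesioncorrect:::augment_lesion_rich(ds, threshold = 5, seed = 11)
  n_rich <- sum(ds$n_lesions > 5)
  expect_identical(nrow(aug), nrow(ds) + n_rich)
  extra <- aug[-seq_len(nrow(ds)), ]
  for (i in seq_len(nrow(extra))) {
    expect_true(all(extra$mask[[i]] %in% 0:2))
    expect_true(all(dim(extra$t2[[i]]) == c(64, 64)))
    # rotated copies keep their source patient (no leakage across patients)
    expect_true(extra$patient_id[i] %in% ds$patient_id)
  }
  # deterministic in the seed
  aug2 <- lesioncorrect:::augment_lesion_rich(ds, threshold = 5, seed = 11)
  expect_identical(aug, aug2)
})

test_that("bounding-box IoU mode matches rectangle arithmetic", {
  a <- matrix(0, 12, 12); a[2:4, 2:4] <- 1   # 3x3 box
  b <- matrix(0, 12, 12); b[3:5, 3:5] <- 1   # shifted by one: overlap 2x2
  ca <- extract_components(a); cb <- extract_components(b)
  expect_equal(instance_iou(ca[1, ], cb[1, ], on = "bbox"), 4 / 14)
  # an L-shape and its bounding box: pixel IoU < bbox IoU
  l <- matrix(0, 12, 12); l[2:6, 2] <- 1; l[6, 2:6] <- 1
  fill <- matrix(0, 12, 12); fill[2:6, 2:6] <- 1
  cl <- extract_components(l); cf <- extract_components(fill)
  expect_equal(instance_iou(cl[1, ], cf[1, ], on = "bbox"), 1)
  expect_lt(instance_iou(cl[1, ], cf[1, ]), 1)
  # matching respects the mode
  m <- match_detections(cl, cf, 0.6, on = "bbox")
  expect_identical(m$tp, 1L)
  m2 <- match_detections(cl, cf, 0.6, on = "pixels")
  expect_identical(m2$tp, 0L) # 9/25 pixel IoU below threshold
})
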