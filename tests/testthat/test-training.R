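test_that("one RMSProp step reproduces the hand-computed update", {
  st <- rmsprop_init(0, alpha = 0.9, eta = 0.01, epsilon = 1e-8)
  u <- rmsprop_update(0, 1, st)
  expect_equal(u$state$mean_sq_grad, 0.1, tolerance = 1e-12)
  expect_equal(u$weights, -0.01 / sqrt(0.1 + 1e-8), tolerance = 1e-10)
})

test_that("zero gradients leave weights unchanged and decay the accumulator", {
  w <- matrix(rnorm(6), 2, 3)
  st <- rmsprop_init(w)
  st$mean_sq_grad <- matrix(2, 2, 3)
  u <- rmsprop_update(w, matrix(0, 2, 3), st)
  expect_identical(u$weights, w)
  expect_equal(u$state$mean_sq_grad, matrix(2 * 0.9, 2, 3))
})

test_that("RMSProp matches a brute-force scalar recurrence over 100 steps", {
  set.seed(10)
  g <- rnorm(100)
  # independent recurrence oracle
  E <- 0; W <- 0.5
  E_trace <- W_trace <- numeric(100)
  for (t in 1:100) {
    E <- 0.9 * E + 0.1 * g[t]^2
    W <- W - 0.01 / sqrt(E + 1e-8) * g[t]
    E_trace[t] <- E
    W_trace[t] <- W
  }
  st <- rmsprop_init(0.5)
  w <- 0.5
  for (t in 1:100) {
    u <- rmsprop_update(w, g[t], st)
    w <- u$weights
    st <- u$state
    expect_equal(st$mean_sq_grad, E_trace[t], tolerance = 1e-12)
    expect_equal(w, W_trace[t], tolerance = 1e-12)
  }
})

test_that("a constant gradient drives the accumulator to g^2", {
  st <- rmsprop_init(0)
  w <- 0
  for (t in 1:400) {
    u <- rmsprop_update(w, 3, st)
    w <- u$weights
    st <- u$state
  }
  expect_equal(st$mean_sq_grad, 9, tolerance = 1e-10)
})

test_that("RMSProp works elementwise over nested weight trees", {
  w <- list(a = matrix(1:4 / 4, 2), b = list(g = rep(0.5, 3)))
  g <- list(a = matrix(1, 2, 2), b = list(g = rep(2, 3)))
  st <- rmsprop_init(w)
  u <- rmsprop_update(w, g, st)
  expect_equal(u$state$mean_sq_grad$a, matrix(0.1, 2, 2))
  expect_equal(u$state$mean_sq_grad$b$g, rep(0.4, 3))
  expect_equal(u$weights$a, w$a - 0.01 / sqrt(0.1 + 1e-8))
  expect_error(rmsprop_update(w, list(a = matrix(1, 2, 2), b = list(g = 1)), st),
               "shape mismatch")
  expect_error(rmsprop_update(0, NaN, rmsprop_init(0)), "non-finite")
})

test_that("cross-entropy reproduces closed forms and rejects bad input", {
  k2 <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(k2, rep(1L, 4)), log(2))
  k3 <- matrix(1 / 3, 4, 3)
  expect_equal(cross_entropy_loss(k3, rep(2L, 4)), log(3))
  onehot <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(cross_entropy_loss(onehot, c(1L, 2L)), 0)
  expect_error(cross_entropy_loss(matrix(c(0.9, 0.9), 1), 1L), "normalized")
  expect_error(cross_entropy_loss(k2, c(1L, 2L, 3L, 1L)), "invalid class")
  # class weights: weighted mean of -log p
  p <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE)
  w <- c(1, 3)
  want <- sum(c(1 * -log(0.8), 3 * -log(0.6))) / 4
  expect_equal(cross_entropy_loss(p, c(1L, 2L), class_weights = w), want)
})

test_that("loss decreases as the true-class probability grows", {
  p_seq <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(p_seq, function(p) {
    cross_entropy_loss(matrix(c(p, 1 - p), 1), 1L)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("primary training is reproducible and learns a separable fixture", {
  cfg <- tiny_phantom_config(image_size = 64)
  set.seed(99)
  slices <- lapply(1:6, function(i) generate_slice(cfg, n_lesions = 6,
                                                   seed = 100 + i))
  ds <- tibble::tibble(
    patient_id = sprintf("P%d", 1:6), slice_id = sprintf("S%d", 1:6),
    t2 = lapply(slices, function(s) s$pair$t2),
    t1 = lapply(slices, function(s) s$pair$t1),
    mask = lapply(slices, function(s) s$mask),
    n_lesions = vapply(slices, function(s) nrow(s$instances), integer(1)))
  spec <- primary_net_spec(depth = 2, base_channels = 4, n_classes = 2,
                           input_size = 64)
  sched <- build_oversample_schedule(ds$n_lesions, 5)
  tcfg <- train_config(epochs_phase1 = 8, epochs_phase2 = 4, batch_size = 1,
                       convergence_patience = 10, seed = 7)
  fit <- train_primary(ds, sched, spec, tcfg)
  fit2 <- train_primary(ds, sched, spec, tcfg)
  expect_identical(fit$net$weights, fit2$net$weights) # seeded determinism
  expect_identical(fit$history, fit2$history)
  # training Dice on the separable noise-free fixture
  dices <- vapply(seq_len(nrow(ds)), function(i) {
    probs <- predict_primary(fit$net, ds$t2[[i]])
    dice_coefficient(probs[, , 2] > probs[, , 1], ds$mask[[i]] > 0)
  }, numeric(1))
  expect_gt(mean(dices), 0.9)
})

test_that("two-phase with equal phases equals single-phase with summed epochs", {
  cfg <- tiny_phantom_config(image_size = 32, lesion_count_range = c(1L, 3L),
                             lesion_radius_range = c(1L, 2L))
  slices <- lapply(1:3, function(i) generate_slice(cfg, seed = 200 + i))
  ds <- tibble::tibble(
    patient_id = sprintf("P%d", 1:3), slice_id = sprintf("S%d", 1:3),
    t2 = lapply(slices, function(s) s$pair$t2),
    mask = lapply(slices, function(s) s$mask),
    n_lesions = vapply(slices, function(s) nrow(s$instances), integer(1)))
  spec <- primary_net_spec(depth = 2, base_channels = 2, n_classes = 2,
                           input_size = 32)
  sched_all <- lesioncorrect:::single_phase_schedule(3)
  tcfg_two <- train_config(epochs_phase1 = 2, epochs_phase2 = 2,
                           batch_size = 2, convergence_patience = 100, seed = 5)
  tcfg_one <- train_config(epochs_phase1 = 0, epochs_phase2 = 4,
                           batch_size = 2, convergence_patience = 100, seed = 5)
  fit_two <- train_primary(ds, sched_all, spec, tcfg_two)
  fit_one <- train_primary(ds, sched_all, spec, tcfg_one)
  expect_identical(fit_two$net$weights, fit_one$net$weights)
  expect_equal(fit_two$history$loss, fit_one$history$loss)
})

test_that("secondary training learns separable ROIs and rejects one class", {
  cfg <- tiny_phantom_config(image_size = 64, class_mix = 0.5)
  rois <- list()
  for (i in 1:12) {
    s <- generate_slice(cfg, n_lesions = 3, seed = 300 + i)
    for (k in seq_len(nrow(s$instances))) {
      rois[[length(rois) + 1L]] <- extract_roi(
        s$pair$t1,
        c(s$instances$centroid_row[k], s$instances$centroid_col[k]),
        true_class = s$instances$class[k])
    }
  }
  classes <- vapply(rois, function(r) r$true_class, character(1))
  expect_true(all(c("FCI", "LACI") %in% classes))
  spec <- secondary_net_spec(base_channels = 8, head = "dense")
  tcfg <- train_config(epochs_phase2 = 15, batch_size = 2, seed = 21)
  fit <- train_secondary(rois, spec, tcfg)
  scores <- predict_secondary(fit$net, lapply(rois, function(r) r$pixels))
  acc <- mean((scores > 0.5) == (classes == "LACI"))
  expect_gt(acc, 0.95)
  # reproducibility and single-class error
  fit2 <- train_secondary(rois, spec, tcfg)
  expect_identical(fit$net$weights, fit2$net$weights)
  expect_error(train_secondary(rois[classes == "FCI"], spec, tcfg),
               "both")
})
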