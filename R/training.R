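#' Training configuration
#'
#' Bundles the two-phase training schedule parameters. Phase 1 pre-trains on
#' the lesion-rich slices of an [build_oversample_schedule()] until the
#' training loss stops improving (no improvement greater than 1e-4 for
#' `convergence_patience` consecutive epochs) or `epochs_phase1` is reached;
#' phase 2 then continues on all training slices for `epochs_phase2` epochs.
#' Setting `epochs_phase1 = 0` yields plain single-phase training.
#'
#' @param epochs_phase1,epochs_phase2 Maximum epochs per phase.
#' @param batch_size Samples per RMSProp update (gradients averaged).
#' @param convergence_patience Epochs without improvement that end phase 1.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_phase1 = 50L, epochs_phase2 = 50L,
                         batch_size = 8L, convergence_patience = 5L,
                         seed = 1L) {
  epochs_phase1 <- as.integer(epochs_phase1)
  epochs_phase2 <- as.integer(epochs_phase2)
  if (epochs_phase1 < 0L || epochs_phase2 < 0L) stop("epoch counts must be >= 0")
  if (batch_size < 1L) stop("`batch_size` must be positive")
  if (convergence_patience < 1L) stop("`convergence_patience` must be positive")
  structure(list(epochs_phase1 = epochs_phase1, epochs_phase2 = epochs_phase2,
                 batch_size = as.integer(batch_size),
                 convergence_patience = as.integer(convergence_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize RMSProp optimizer state
#'
#' @param weights A numeric array or a nested list of numeric arrays; the
#'   squared-gradient accumulator is created with the same shape, all zeros.
#' @param alpha Moving-average parameter of the squared-gradient accumulator
#'   (default 0.9).
#' @param eta Base learning rate (default 0.01).
#' @param epsilon Guard added under the square root to prevent division by
#'   zero (default 1e-8).
#' @return An object of class `optimizer_state`.
#' @seealso [rmsprop_update()]
#' @export
rmsprop_init <- function(weights, alpha = 0.9, eta = 0.01, epsilon = 1e-8) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (eta <= 0) stop("`eta` must be positive")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  structure(list(mean_sq_grad = tree_zeros_like(weights),
                 alpha = alpha, eta = eta, epsilon = epsilon),
            class = "optimizer_state")
}

#' One RMSProp update step
#'
#' Applies the RMSProp recurrence: the accumulator becomes
#' `E' = alpha * E + (1 - alpha) * g^2` elementwise, and the weights become
#' `W' = W - eta / sqrt(E' + epsilon) * g`, using the updated accumulator.
#' Works on a plain numeric array or on a nested list of arrays (the whole
#' parameter tree of a network).
#'
#' @param weights Numeric array or nested list of arrays.
#' @param grad Gradient with the same shape as `weights`.
#' @param state An [rmsprop_init()] state whose accumulator matches `weights`.
#' @return A list with updated `weights` and `state`.
#' @examples
#' st <- rmsprop_init(0)
#' rmsprop_update(0, 1, st) # weights move to -0.01/sqrt(0.1 + 1e-8)
#' @export
rmsprop_update <- function(weights, grad, state) {
  stopifnot(inherits(state, "optimizer_state"))
  check_pair <- function(w, g, e) {
    if (length(w) != length(g) || length(w) != length(e)) {
      stop("shape mismatch between weights, gradient and optimizer state")
    }
    if (any(!is.finite(g))) stop("non-finite gradient")
  }
  alpha <- state$alpha; eta <- state$eta; eps <- state$epsilon
  if (is.list(weights)) {
    # walk the three trees (weights, grad, accumulator) together
    walk3 <- function(w, g, e) {
      if (is.list(w)) {
        ws <- vector("list", length(w)); names(ws) <- names(w)
        es <- vector("list", length(w)); names(es) <- names(w)
        for (i in seq_along(w)) {
          r <- walk3(w[[i]], g[[i]], e[[i]])
          ws[[i]] <- r$w; es[[i]] <- r$e
        }
        list(w = ws, e = es)
      } else {
        check_pair(w, g, e)
        e2 <- alpha * e + (1 - alpha) * g * g
        list(w = w - eta / sqrt(e2 + eps) * g, e = e2)
      }
    }
    r <- walk3(weights, grad, state$mean_sq_grad)
    state$mean_sq_grad <- r$e
    list(weights = r$w, state = state)
  } else {
    check_pair(weights, grad, state$mean_sq_grad)
    e2 <- alpha * state$mean_sq_grad + (1 - alpha) * grad * grad
    state$mean_sq_grad <- e2
    list(weights = weights - eta / sqrt(e2 + eps) * grad, state = state)
  }
}

#' Cross-entropy loss
#'
#' Mean of `-log p(true class)` over all pixels/samples, with optional class
#' weights (a weighted mean, normalized by the total weight).
#'
#' @param predicted_probs Array whose last dimension indexes classes (e.g.
#'   H x W x K pixelwise probabilities, or an N x K matrix).
#' @param true_labels Integer array of class indices in `1..K`, one per
#'   pixel/sample (shape = `predicted_probs` without its last dimension).
#' @param class_weights Optional length-K nonnegative weights.
#' @return Nonnegative scalar; 0 iff every true class has probability 1.
#' @examples
#' cross_entropy_loss(matrix(0.5, 1, 2), 1L) # log(2)
#' @export
cross_entropy_loss <- function(predicted_probs, true_labels,
                               class_weights = NULL) {
  d <- dim(predicted_probs)
  if (is.null(d)) stop("`predicted_probs` must have a class dimension")
  k <- d[length(d)]
  n <- prod(d) / k
  m <- matrix(predicted_probs, n, k)
  lab <- as.integer(true_labels)
  if (length(lab) != n) stop("labels do not match the probability grid")
  if (any(lab < 1L | lab > k)) stop("invalid class labels")
  if (any(m < 0) || max(abs(rowSums(m) - 1)) > 1e-5) {
    stop("`predicted_probs` are not normalized probabilities")
  }
  p <- m[cbind(seq_len(n), lab)]
  if (any(p <= 0)) return(Inf)
  if (is.null(class_weights)) {
    mean(-log(p))
  } else {
    if (length(class_weights) != k || any(class_weights < 0)) {
      stop("`class_weights` must be ", k, " nonnegative values")
    }
    w <- class_weights[lab]
    sum(-w * log(p)) / sum(w)
  }
}

# loss + gradient for one slice through the primary net. labels: H x W in 1..K.
primary_loss_grad <- function(net, t2, labels, class_weights = NULL) {
  fw <- primary_forward(net, t2, training = TRUE)
  net$bn <- fw$bn
  d <- dim(fw$probs)
  n <- d[1L] * d[2L]
  k <- d[3L]
  pm <- matrix(fw$probs, n, k)
  lab <- as.integer(labels)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), lab)] <- 1
  if (is.null(class_weights)) {
    dlogits <- (pm - onehot) / n
    loss <- -mean(log(pmax(pm[cbind(seq_len(n), lab)], 1e-12)))
  } else {
    w <- class_weights[lab]
    dlogits <- (pm - onehot) * w / sum(w)
    loss <- sum(-w * log(pmax(pm[cbind(seq_len(n), lab)], 1e-12))) / sum(w)
  }
  grads <- primary_backward(net, fw$cache, array(dlogits, d))
  list(loss = loss, grads = grads, bn = fw$bn)
}

# generic two-phase mini-batch RMSProp loop shared by both trainers.
run_epochs <- function(items, loss_grad_fn, weights, state, epochs, batch_size,
                       phase, patience = Inf, min_improve = 1e-4,
                       apply_bn = NULL) {
  history <- list()
  best <- Inf
  wait <- 0L
  n <- length(items)
  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(i + batch_size - 1L, n)]
      acc <- NULL
      for (j in batch) {
        r <- loss_grad_fn(items[[j]], weights)
        if (!is.null(apply_bn)) apply_bn(r)
        acc <- if (is.null(acc)) r$grads else tree_add(acc, r$grads)
        losses <- c(losses, r$loss)
      }
      upd <- rmsprop_update(weights, tree_scale(acc, 1 / length(batch)), state)
      weights <- upd$weights
      state <- upd$state
      i <- i + batch_size
    }
    ep_loss <- mean(losses)
    history[[epoch]] <- tibble::tibble(phase = phase, epoch = epoch,
                                       loss = ep_loss)
    if (is.finite(patience)) {
      if (best - ep_loss > min_improve) {
        best <- ep_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  list(weights = weights, state = state,
       history = dplyr::bind_rows(history))
}

#' Train the primary segmentation network
#'
#' Two-phase RMSProp training with cross-entropy loss: phase 1 pre-trains on
#' the lesion-rich slices of the oversampling schedule until convergence
#' (patience rule) or `epochs_phase1`; phase 2 continues on all training
#' slices for `epochs_phase2` epochs. The run is reproducible from
#' `cfg$seed`.
#'
#' @param dataset A phantom dataset tibble (see [generate_dataset()]) or any
#'   tibble with list-columns `t2` and `mask`; rows are the training fold.
#' @param schedule An [build_oversample_schedule()] over the rows of
#'   `dataset`.
#' @param spec A [primary_net_spec()]; `n_classes = 2` trains on the binary
#'   lesion mask, `n_classes = 3` on the full background/FCI/LACI labels.
#' @param cfg A [train_config()].
#' @param class_weights Optional per-class loss weights (default none; the
#'   oversampling schedule is the primary class-imbalance remedy).
#' @param alpha,eta,epsilon RMSProp parameters, see [rmsprop_init()].
#' @return An object of class `primary_fit`: the trained `net` plus a
#'   `history` tibble with per-epoch losses for both phases.
#' @export
train_primary <- function(dataset, schedule, spec, cfg, class_weights = NULL,
                          alpha = 0.9, eta = 0.01, epsilon = 1e-8) {
  stopifnot(inherits(spec, "primary_net_spec"), inherits(cfg, "train_config"))
  if (nrow(dataset) == 0L) stop("training fold is empty")
  stopifnot(inherits(schedule, "oversample_schedule"))
  set.seed(cfg$seed)
  net <- build_primary(spec)
  state <- rmsprop_init(net$weights, alpha, eta, epsilon)
  items <- purrr::map(seq_len(nrow(dataset)), function(i) {
    m <- dataset$mask[[i]]
    labels <- if (spec$n_classes == 2L) (m > 0L) + 1L else m + 1L
    list(t2 = dataset$t2[[i]], labels = labels)
  })
  loss_grad <- function(item, weights) {
    net$weights <- weights
    r <- primary_loss_grad(net, item$t2, item$labels, class_weights)
    net$bn <<- r$bn
    r
  }
  hist1 <- NULL
  weights <- net$weights
  if (cfg$epochs_phase1 > 0L) {
    r1 <- run_epochs(items[schedule$phase1_indices], loss_grad, weights, state,
                     cfg$epochs_phase1, cfg$batch_size, "phase1",
                     patience = cfg$convergence_patience)
    weights <- r1$weights
    state <- r1$state
    hist1 <- r1$history
  }
  r2 <- run_epochs(items[schedule$phase2_indices], loss_grad, weights, state,
                   cfg$epochs_phase2, cfg$batch_size, "phase2")
  net$weights <- r2$weights
  structure(list(net = net, history = dplyr::bind_rows(hist1, r2$history),
                 cfg = cfg),
            class = "primary_fit")
}

#' Train the secondary correction network
#'
#' Binary cross-entropy training on P(LACI) over labelled ROI patches with
#' RMSProp; single-phase, `cfg$epochs_phase2` epochs, reproducible from
#' `cfg$seed`.
#'
#' @param roi_set A list of [extract_roi()] patches carrying `true_class`
#'   (`"FCI"`/`"LACI"`), or a tibble with list-column `roi` and column
#'   `true_class`. Must contain both classes.
#' @param spec A [secondary_net_spec()].
#' @param cfg A [train_config()].
#' @inheritParams train_primary
#' @return An object of class `secondary_fit`: trained `net` plus a
#'   `history` tibble (per-epoch loss and training accuracy).
#' @export
train_secondary <- function(roi_set, spec, cfg,
                            alpha = 0.9, eta = 0.01, epsilon = 1e-8) {
  stopifnot(inherits(spec, "secondary_net_spec"), inherits(cfg, "train_config"))
  if (is.data.frame(roi_set)) {
    roi_set <- purrr::map2(roi_set$roi, roi_set$true_class, function(r, cl) {
      r$true_class <- cl
      r
    })
  }
  classes <- vapply(roi_set, function(r) r$true_class, character(1))
  if (length(unique(classes)) < 2L) {
    stop("secondary training set must contain both FCI and LACI ROIs")
  }
  set.seed(cfg$seed)
  net <- build_secondary(spec)
  state <- rmsprop_init(net$weights, alpha, eta, epsilon)
  items <- purrr::map(roi_set, function(r) {
    list(x = r$pixels, y = as.numeric(r$true_class == "LACI"))
  })
  loss_grad <- function(item, weights) {
    net$weights <- weights
    fw <- secondary_forward(net, item$x, training = TRUE)
    s <- fw$score
    loss <- -(item$y * log(max(s, 1e-12)) +
                (1 - item$y) * log(max(1 - s, 1e-12)))
    grads <- secondary_backward(net, fw$cache, s - item$y)
    list(loss = loss, grads = grads, correct = (s > 0.5) == (item$y > 0.5))
  }
  n <- length(items)
  history <- list()
  weights <- net$weights
  for (epoch in seq_len(cfg$epochs_phase2)) {
    ord <- sample(n)
    losses <- numeric(0)
    correct <- logical(0)
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, n)]
      acc <- NULL
      for (j in batch) {
        r <- loss_grad(items[[j]], weights)
        acc <- if (is.null(acc)) r$grads else tree_add(acc, r$grads)
        losses <- c(losses, r$loss)
        correct <- c(correct, r$correct)
      }
      upd <- rmsprop_update(weights, tree_scale(acc, 1 / length(batch)), state)
      weights <- upd$weights
      state <- upd$state
      i <- i + cfg$batch_size
    }
    history[[epoch]] <- tibble::tibble(phase = "train", epoch = epoch,
                                       loss = mean(losses),
                                       accuracy = mean(correct))
  }
  net$weights <- weights
  structure(list(net = net, history = dplyr::bind_rows(history), cfg = cfg),
            class = "secondary_fit")
}

#' @export
print.primary_fit <- function(x, ...) {
  cat("Trained primary network;", nrow(x$history), "epochs, final loss",
      signif(utils::tail(x$history$loss, 1), 4), "\n")
  invisible(x)
}

#' @export
print.secondary_fit <- function(x, ...) {
  cat("Trained secondary network;", nrow(x$history), "epochs, final accuracy",
      signif(utils::tail(x$history$accuracy, 1), 4), "\n")
  invisible(x)
}
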