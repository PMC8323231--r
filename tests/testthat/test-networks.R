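test_that("primary network outputs full-size per-pixel probabilities", {
  set.seed(1)
  spec <- primary_net_spec(depth = 3, base_channels = 2, n_classes = 3,
                           input_size = 32)
  net <- build_primary(spec)
  p <- predict_primary(net, matrix(runif(32 * 32), 32, 32))
  expect_identical(dim(p), c(32L, 32L, 3L))
  sums <- apply(p, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("the encoder of a depth-5 net has exactly ten 3x3 convolutions", {
  set.seed(1)
  net <- build_primary(primary_net_spec(depth = 5, base_channels = 2,
                                        n_classes = 2, input_size = 32))
  enc_convs <- dplyr::filter(net$layers, .data$stage == "encoder",
                             .data$type == "conv", .data$kernel == 3L)
  expect_identical(nrow(enc_convs), 10L)
  # one max-pool per level except the deepest
  expect_identical(sum(net$layers$type == "maxpool"), 4L)
})

test_that("zero weights give a uniform softmax everywhere", {
  set.seed(2)
  for (k in 2:3) {
    spec <- primary_net_spec(depth = 2, base_channels = 1, n_classes = k,
                             input_size = 16)
    net <- build_primary(spec)
    net$weights <- lesioncorrect:::tree_map(net$weights, function(x) x * 0)
    p <- predict_primary(net, matrix(runif(256), 16, 16))
    expect_equal(as.vector(p), rep(1 / k, length(p)))
  }
})

test_that("input sizes not divisible by 2^(depth-1) are rejected", {
  expect_error(primary_net_spec(depth = 4, input_size = 100), "divisible")
  expect_error(primary_net_spec(depth = 1), "at least 2")
  expect_error(primary_net_spec(n_classes = 4), "2 or 3")
})

test_that("parameter count matches a hand-derived formula for small specs", {
  count_primary <- function(depth, c1, k) {
    ch <- c1 * 2^(seq_len(depth) - 1)
    total <- 0
    for (l in seq_len(depth)) {
      cin <- if (l == 1) 1 else ch[l - 1]
      total <- total + (9 * cin * ch[l] + ch[l]) + 2 * ch[l] + # conv a + bn
        (9 * ch[l] * ch[l] + ch[l]) + 2 * ch[l]                # conv b + bn
    }
    for (l in seq_len(depth - 1)) {
      total <- total + (4 * ch[l + 1] * ch[l] + ch[l]) + 2 * ch[l] + # upconv+bn
        (9 * 2 * ch[l] * ch[l] + ch[l]) + 2 * ch[l] +
        (9 * ch[l] * ch[l] + ch[l]) + 2 * ch[l]
    }
    total + (ch[1]^2 + ch[1]) + (ch[1] * k + k)
  }
  set.seed(3)
  for (cfg in list(c(2, 2, 2), c(3, 2, 3), c(2, 4, 2))) {
    spec <- primary_net_spec(cfg[1], cfg[2], cfg[3], input_size = 16)
    net <- build_primary(spec)
    expect_identical(n_parameters(net),
                     as.integer(count_primary(cfg[1], cfg[2], cfg[3])))
  }
})

test_that("secondary network maps any ROI to a probability", {
  set.seed(4)
  net <- build_secondary(secondary_net_spec(base_channels = 2))
  s <- predict_secondary(net, matrix(runif(64 * 64), 64, 64))
  expect_true(s >= 0 && s <= 1)
  expect_error(predict_secondary(net, matrix(0.5, 32, 32)), "64x64")
})

test_that("zero secondary weights give exactly 0.5", {
  set.seed(5)
  for (head in c("conv1x1", "dense")) {
    net <- build_secondary(secondary_net_spec(base_channels = 2, head = head))
    net$weights <- lesioncorrect:::tree_map(net$weights, function(x) x * 0)
    expect_identical(predict_secondary(net, matrix(0.7, 64, 64)), 0.5)
  }
})

test_that("batched secondary scoring preserves order", {
  set.seed(6)
  net <- build_secondary(secondary_net_spec(base_channels = 2))
  rois <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  batch <- predict_secondary(net, rois)
  single <- vapply(rois, function(r) predict_secondary(net, r), numeric(1))
  expect_identical(batch, single)
})

test_that("inference is deterministic and dropout is inference-silent", {
  set.seed(7)
  net <- build_secondary(secondary_net_spec(base_channels = 2,
                                            dropout_rate = 0.5))
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(predict_secondary(net, x), predict_secondary(net, x))
  # training mode with dropout differs across draws
  set.seed(1)
  a <- lesioncorrect:::secondary_forward(net, x, training = TRUE)$score
  b <- lesioncorrect:::secondary_forward(net, x, training = TRUE)$score
  expect_false(identical(a, b))
})

test_that("primary network is translation-consistent away from borders", {
  set.seed(8)
  spec <- primary_net_spec(depth = 2, base_channels = 4, n_classes = 2,
                           input_size = 32)
  net <- build_primary(spec)
  x <- matrix(0.1, 32, 32)
  x[10:13, 10:13] <- 0.9
  shift <- 2L # one pooling stride
  xs <- matrix(0.1, 32, 32)
  xs[(10 + shift):(13 + shift), 10:13] <- 0.9
  p <- predict_primary(net, x)
  ps <- predict_primary(net, xs)
  inner <- 9:20 # region far from both borders
  expect_lt(max(abs(p[inner, inner, 2] - ps[inner + shift, inner, 2])), 1e-8)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(31)
  spec <- primary_net_spec(depth = 2, base_channels = 2, n_classes = 2,
                           input_size = 8)
  net <- build_primary(spec)
  # jitter biases so no ReLU sits exactly at its kink
  net$weights <- lesioncorrect:::tree_map(net$weights,
                                          function(x) x + rnorm(length(x), sd = 0.05))
  x <- matrix(runif(64), 8, 8)
  labels <- matrix(sample(1:2, 64, TRUE), 8, 8)
  r <- lesioncorrect:::primary_loss_grad(net, x, labels)
  w0 <- unlist(net$weights, use.names = FALSE)
  g0 <- unlist(r$grads, use.names = FALSE)
  set_flat <- function(tr, vec) {
    i <- 0L
    walk <- function(x) {
      if (is.list(x)) return(lapply(x, walk))
      n <- length(x)
      out <- vec[(i + 1L):(i + n)]
      i <<- i + n
      if (is.null(dim(x))) out else array(out, dim(x))
    }
    walk(tr)
  }
  loss_at <- function(wvec) {
    n2 <- net
    n2$weights <- set_flat(net$weights, wvec)
    fw <- lesioncorrect:::primary_forward(n2, x, training = TRUE)
    pm <- matrix(fw$probs, 64, 2)
    -mean(log(pm[cbind(1:64, as.integer(labels))]))
  }
  eps <- 1e-5
  idx <- sample(length(w0), 25)
  for (i in idx) {
    wp <- w0; wp[i] <- wp[i] + eps
    wm <- w0; wm[i] <- wm[i] - eps
    gn <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    expect_lt(abs(gn - g0[i]) / max(abs(gn) + abs(g0[i]), 1e-6), 1e-3)
  }
})
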