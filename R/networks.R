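#' Specification of the primary segmentation network
#'
#' The primary network is a symmetric encoder--decoder (U-Net family) that
#' maps a single-channel T2 FLAIR slice to per-pixel class probabilities.
#' Each encoder level applies two 3x3 same-padding convolutions, each
#' followed by batch normalization and ReLU; a 2x2 max-pool follows every
#' level except the deepest. The decoder mirrors the encoder with 2x2
#' stride-2 transposed convolutions that halve the channel count (+ BN +
#' ReLU), concatenation with the matching encoder feature map, and two more
#' conv+BN+ReLU blocks. The head is two consecutive 1x1 convolutions and a
#' channel-wise softmax. At the default `depth = 5` the encoder contains
#' exactly ten 3x3 convolutions.
#'
#' @param depth Number of encoder levels (>= 2). Default 5.
#' @param base_channels Feature maps at the first level; doubled at each
#'   deeper level. Default 64; use 8 for a fast CPU preset.
#' @param n_classes 2 for binary lesion/background segmentation (task "b"),
#'   3 for one-stage semantic segmentation background/FCI/LACI (task "a").
#' @param input_size Image side length in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @return An object of class `primary_net_spec`.
#' @seealso [build_primary()]
#' @export
primary_net_spec <- function(depth = 5L, base_channels = 64L, n_classes = 2L,
                             input_size = 128L) {
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  n_classes <- as.integer(n_classes)
  input_size <- as.integer(input_size)
  if (depth < 2L) stop("`depth` must be at least 2")
  if (!n_classes %in% c(2L, 3L)) stop("`n_classes` must be 2 or 3")
  if (base_channels < 1L) stop("`base_channels` must be positive")
  if (input_size %% 2L^(depth - 1L) != 0L) {
    stop("`input_size` must be divisible by 2^(depth - 1)")
  }
  structure(list(depth = depth, base_channels = base_channels,
                 n_classes = n_classes, input_size = input_size),
            class = "primary_net_spec")
}

#' Specification of the secondary correction network
#'
#' The secondary network classifies one 64x64 gamma-transformed T1 ROI as
#' FCI or LACI, emitting a single probability P(LACI) through a sigmoid.
#' It has five 3x3 convolutions with ReLU, three 2x2 pooling layers
#' (average by default, max selectable), and one of two heads: global
#' average pooling followed by two 1x1 convolutions (default), or two
#' fully-connected layers on the flattened feature map. Dropout is applied
#' inside the head during training only.
#'
#' @param base_channels Channels of the first convolution (doubled twice
#'   down the stack). Default 16; use 8 for a fast CPU preset.
#' @param pooling `"average"` (default) or `"max"`.
#' @param head `"conv1x1"` (default) or `"dense"`.
#' @param dropout_rate Dropout probability in the head, default 0.5.
#' @param input_size Must be 64.
#' @return An object of class `secondary_net_spec`.
#' @seealso [build_secondary()]
#' @export
secondary_net_spec <- function(base_channels = 16L,
                               pooling = c("average", "max"),
                               head = c("conv1x1", "dense"),
                               dropout_rate = 0.5, input_size = 64L) {
  pooling <- match.arg(pooling)
  head <- match.arg(head)
  input_size <- as.integer(input_size)
  if (input_size != 64L) stop("`input_size` must be 64")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must be in [0, 1)")
  structure(list(n_conv = 5L, kernel = 3L,
                 base_channels = as.integer(base_channels), pooling = pooling,
                 head = head, dropout_rate = dropout_rate,
                 input_size = input_size),
            class = "secondary_net_spec")
}

new_conv <- function(cin, cout, kernel = 3L) {
  list(W = he_init(c(kernel * kernel * cin, cout), kernel * kernel * cin),
       b = numeric(cout))
}

new_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

new_upconv <- function(cin, cout) {
  list(W = he_init(c(cin, cout, 4L), 4L * cin), b = numeric(cout))
}

#' Build (initialize) the primary segmentation network
#'
#' Instantiates the weights of a [primary_net_spec()] with He-normal
#' initialization drawn from the current RNG stream (seed it for
#' reproducibility). The returned object carries the weights, the batch-norm
#' running statistics, and a layer table for introspection.
#'
#' @param spec A [primary_net_spec()].
#' @return An object of class `primary_net` with elements `spec`, `weights`
#'   (nested list of arrays), `bn` (running statistics), and `layers`
#'   (a tibble describing every layer).
#' @examples
#' set.seed(1)
#' net <- build_primary(primary_net_spec(depth = 2, base_channels = 2,
#'                                       input_size = 16))
#' net$layers
#' @export
build_primary <- function(spec) {
  stopifnot(inherits(spec, "primary_net_spec"))
  d <- spec$depth
  ch <- spec$base_channels * 2L^(seq_len(d) - 1L)
  weights <- list(enc = vector("list", d), up = list(), dec = list(),
                  head1 = NULL, head2 = NULL)
  bn <- list(enc = vector("list", d), up = list(), dec = list())
  layers <- list()
  add_layer <- function(name, type, kernel, cin, cout, stage) {
    layers[[length(layers) + 1L]] <<- tibble::tibble(
      name = name, type = type, kernel = kernel,
      in_ch = cin, out_ch = cout, stage = stage)
  }
  for (l in seq_len(d)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    weights$enc[[l]] <- list(a = new_conv(cin, ch[l]), bna = new_bn(ch[l]),
                             b = new_conv(ch[l], ch[l]), bnb = new_bn(ch[l]))
    bn$enc[[l]] <- list(a = bn_init_running(ch[l]), b = bn_init_running(ch[l]))
    add_layer(paste0("enc", l, "a"), "conv", 3L, cin, ch[l], "encoder")
    add_layer(paste0("enc", l, "b"), "conv", 3L, ch[l], ch[l], "encoder")
    if (l < d) add_layer(paste0("pool", l), "maxpool", 2L, ch[l], ch[l], "encoder")
  }
  for (l in rev(seq_len(d - 1L))) {
    key <- as.character(l)
    weights$up[[key]] <- list(conv = new_upconv(ch[l + 1L], ch[l]),
                              bn = new_bn(ch[l]))
    weights$dec[[key]] <- list(a = new_conv(2L * ch[l], ch[l]),
                               bna = new_bn(ch[l]),
                               b = new_conv(ch[l], ch[l]),
                               bnb = new_bn(ch[l]))
    bn$up[[key]] <- bn_init_running(ch[l])
    bn$dec[[key]] <- list(a = bn_init_running(ch[l]), b = bn_init_running(ch[l]))
    add_layer(paste0("up", l), "upconv", 2L, ch[l + 1L], ch[l], "decoder")
    add_layer(paste0("dec", l, "a"), "conv", 3L, 2L * ch[l], ch[l], "decoder")
    add_layer(paste0("dec", l, "b"), "conv", 3L, ch[l], ch[l], "decoder")
  }
  weights$head1 <- list(W = he_init(c(ch[1L], ch[1L]), ch[1L]),
                        b = numeric(ch[1L]))
  weights$head2 <- list(W = he_init(c(ch[1L], spec$n_classes), ch[1L]),
                        b = numeric(spec$n_classes))
  add_layer("head1", "conv", 1L, ch[1L], ch[1L], "head")
  add_layer("head2", "conv", 1L, ch[1L], spec$n_classes, "head")
  structure(list(spec = spec, weights = weights, bn = bn,
                 layers = dplyr::bind_rows(layers)),
            class = "primary_net")
}

# Full forward pass. training = TRUE caches intermediates for the backward
# pass and updates BN running stats (returned in $bn).
primary_forward <- function(net, x, training = FALSE) {
  spec <- net$spec
  w <- net$weights
  bn <- net$bn
  d <- spec$depth
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  cache <- list(enc = vector("list", d), pool = vector("list", d - 1L),
                up = list(), dec = list())
  skips <- vector("list", d)
  h <- x
  for (l in seq_len(d)) {
    cl <- list()
    ca <- conv3x3_forward(h, w$enc[[l]]$a$W, w$enc[[l]]$a$b, training)
    ba <- bn_forward(ca$y, w$enc[[l]]$bna$gamma, w$enc[[l]]$bna$beta,
                     bn$enc[[l]]$a, training)
    bn$enc[[l]]$a <- ba$running
    ra <- relu_forward(ba$y)
    cb <- conv3x3_forward(ra$y, w$enc[[l]]$b$W, w$enc[[l]]$b$b, training)
    bb <- bn_forward(cb$y, w$enc[[l]]$bnb$gamma, w$enc[[l]]$bnb$beta,
                     bn$enc[[l]]$b, training)
    bn$enc[[l]]$b <- bb$running
    rb <- relu_forward(bb$y)
    skips[[l]] <- rb$y
    if (training) {
      cache$enc[[l]] <- list(ca = ca$cache, ba = ba$cache, ra = ra$cache,
                             cb = cb$cache, bb = bb$cache, rb = rb$cache)
    }
    if (l < d) {
      mp <- maxpool2_forward(rb$y)
      if (training) cache$pool[[l]] <- mp$cache
      h <- mp$y
    } else {
      h <- rb$y
    }
  }
  for (l in rev(seq_len(d - 1L))) {
    key <- as.character(l)
    uc <- upconv2_forward(h, w$up[[key]]$conv$W, w$up[[key]]$conv$b)
    ub <- bn_forward(uc$y, w$up[[key]]$bn$gamma, w$up[[key]]$bn$beta,
                     bn$up[[key]], training)
    bn$up[[key]] <- ub$running
    ur <- relu_forward(ub$y)
    sk <- skips[[l]]
    cat_y <- array(c(sk, ur$y), c(dim(sk)[1:2], dim(sk)[3L] + dim(ur$y)[3L]))
    ca <- conv3x3_forward(cat_y, w$dec[[key]]$a$W, w$dec[[key]]$a$b, training)
    ba <- bn_forward(ca$y, w$dec[[key]]$bna$gamma, w$dec[[key]]$bna$beta,
                     bn$dec[[key]]$a, training)
    bn$dec[[key]]$a <- ba$running
    ra <- relu_forward(ba$y)
    cb <- conv3x3_forward(ra$y, w$dec[[key]]$b$W, w$dec[[key]]$b$b, training)
    bb <- bn_forward(cb$y, w$dec[[key]]$bnb$gamma, w$dec[[key]]$bnb$beta,
                     bn$dec[[key]]$b, training)
    bn$dec[[key]]$b <- bb$running
    rb <- relu_forward(bb$y)
    if (training) {
      cache$up[[key]] <- list(uc = uc$cache, ub = ub$cache, ur = ur$cache,
                              n_skip = dim(sk)[3L])
      cache$dec[[key]] <- list(ca = ca$cache, ba = ba$cache, ra = ra$cache,
                               cb = cb$cache, bb = bb$cache, rb = rb$cache)
    }
    h <- rb$y
  }
  h1 <- conv1x1_forward(h, w$head1$W, w$head1$b)
  r1 <- relu_forward(h1$y)
  h2 <- conv1x1_forward(r1$y, w$head2$W, w$head2$b)
  probs <- softmax_channels(h2$y)
  if (training) {
    cache$h1 <- h1$cache; cache$r1 <- r1$cache; cache$h2 <- h2$cache
  }
  list(probs = probs, logits = h2$y, cache = cache, bn = bn)
}

# Backward pass from d(loss)/d(logits); returns gradients shaped like weights.
primary_backward <- function(net, cache, dlogits) {
  spec <- net$spec
  w <- net$weights
  d <- spec$depth
  g <- tree_zeros_like(w)
  b2 <- conv1x1_backward(dlogits, cache$h2, w$head2$W)
  g$head2$W <- b2$dW; g$head2$b <- b2$db
  dr1 <- relu_backward(b2$dx, cache$r1)
  b1 <- conv1x1_backward(dr1, cache$h1, w$head1$W)
  g$head1$W <- b1$dW; g$head1$b <- b1$db
  dh <- b1$dx
  dskips <- vector("list", d)
  for (l in seq_len(d - 1L)) {
    key <- as.character(l)
    cc <- cache$dec[[key]]
    drb <- relu_backward(dh, cc$rb)
    bb <- bn_backward(drb, cc$bb)
    g$dec[[key]]$bnb$gamma <- bb$dgamma; g$dec[[key]]$bnb$beta <- bb$dbeta
    cb <- conv3x3_backward(bb$dx, cc$cb, w$dec[[key]]$b$W)
    g$dec[[key]]$b$W <- cb$dW; g$dec[[key]]$b$b <- cb$db
    dra <- relu_backward(cb$dx, cc$ra)
    ba <- bn_backward(dra, cc$ba)
    g$dec[[key]]$bna$gamma <- ba$dgamma; g$dec[[key]]$bna$beta <- ba$dbeta
    ca <- conv3x3_backward(ba$dx, cc$ca, w$dec[[key]]$a$W)
    g$dec[[key]]$a$W <- ca$dW; g$dec[[key]]$a$b <- ca$db
    cu <- cache$up[[key]]
    n_skip <- cu$n_skip
    dcat <- ca$dx
    dskips[[l]] <- dcat[, , seq_len(n_skip), drop = FALSE]
    dur <- dcat[, , (n_skip + 1L):dim(dcat)[3L], drop = FALSE]
    dub <- relu_backward(dur, cu$ur)
    ub <- bn_backward(dub, cu$ub)
    g$up[[key]]$bn$gamma <- ub$dgamma; g$up[[key]]$bn$beta <- ub$dbeta
    uc <- upconv2_backward(ub$dx, cu$uc, w$up[[key]]$conv$W)
    g$up[[key]]$conv$W <- uc$dW; g$up[[key]]$conv$b <- uc$db
    dh <- uc$dx
  }
  for (l in rev(seq_len(d))) {
    dskip <- if (l == d) dh else {
      maxpool2_backward(dh, cache$pool[[l]]) + dskips[[l]]
    }
    ce <- cache$enc[[l]]
    drb <- relu_backward(dskip, ce$rb)
    bb <- bn_backward(drb, ce$bb)
    g$enc[[l]]$bnb$gamma <- bb$dgamma; g$enc[[l]]$bnb$beta <- bb$dbeta
    cb <- conv3x3_backward(bb$dx, ce$cb, w$enc[[l]]$b$W)
    g$enc[[l]]$b$W <- cb$dW; g$enc[[l]]$b$b <- cb$db
    dra <- relu_backward(cb$dx, ce$ra)
    ba <- bn_backward(dra, ce$ba)
    g$enc[[l]]$bna$gamma <- ba$dgamma; g$enc[[l]]$bna$beta <- ba$dbeta
    ca <- conv3x3_backward(ba$dx, ce$ca, w$enc[[l]]$a$W, want_dx = l > 1L)
    g$enc[[l]]$a$W <- ca$dW; g$enc[[l]]$a$b <- ca$db
    dh <- ca$dx
  }
  g
}

#' Segment a slice with the primary network
#'
#' Runs the primary network in inference mode (batch-norm running statistics,
#' no dropout) and returns per-pixel class probabilities.
#'
#' @param net A `primary_net` (possibly trained; see [train_primary()]).
#' @param t2 A matrix of T2 intensities in `[0, 1]` whose side equals
#'   `net$spec$input_size` (any size divisible by `2^(depth-1)` works).
#' @return An H x W x n_classes array of probabilities summing to 1 at every
#'   pixel; class 1 is background.
#' @export
predict_primary <- function(net, t2) {
  stopifnot(inherits(net, "primary_net"))
  primary_forward(net, t2, training = FALSE)$probs
}

#' Build (initialize) the secondary correction network
#'
#' @param spec A [secondary_net_spec()].
#' @return An object of class `secondary_net` with `spec`, `weights`, and a
#'   `layers` tibble.
#' @export
build_secondary <- function(spec) {
  stopifnot(inherits(spec, "secondary_net_spec"))
  c1 <- spec$base_channels
  ch <- c(c1, 2L * c1, 2L * c1, 4L * c1, 4L * c1)
  weights <- list(conv = vector("list", 5L))
  layers <- list()
  cin <- 1L
  for (i in 1:5) {
    weights$conv[[i]] <- new_conv(cin, ch[i])
    layers[[length(layers) + 1L]] <- tibble::tibble(
      name = paste0("conv", i), type = "conv", kernel = 3L,
      in_ch = cin, out_ch = ch[i], stage = "features")
    if (i <= 3L) {
      layers[[length(layers) + 1L]] <- tibble::tibble(
        name = paste0("pool", i), type = spec$pooling, kernel = 2L,
        in_ch = ch[i], out_ch = ch[i], stage = "features")
    }
    cin <- ch[i]
  }
  hidden <- 2L * c1
  if (spec$head == "conv1x1") {
    weights$fc1 <- list(W = he_init(c(ch[5L], hidden), ch[5L]),
                        b = numeric(hidden))
    weights$fc2 <- list(W = he_init(c(hidden, 1L), hidden), b = numeric(1L))
    layers[[length(layers) + 1L]] <- tibble::tibble(
      name = "gap", type = "global_avgpool", kernel = NA_integer_,
      in_ch = ch[5L], out_ch = ch[5L], stage = "head")
    in1 <- ch[5L]
  } else {
    flat <- 8L * 8L * ch[5L]
    weights$fc1 <- list(W = he_init(c(flat, hidden), flat), b = numeric(hidden))
    weights$fc2 <- list(W = he_init(c(hidden, 1L), hidden), b = numeric(1L))
    in1 <- flat
  }
  layers[[length(layers) + 1L]] <- tibble::tibble(
    name = "fc1", type = if (spec$head == "conv1x1") "conv" else "dense",
    kernel = if (spec$head == "conv1x1") 1L else NA_integer_,
    in_ch = in1, out_ch = hidden, stage = "head")
  layers[[length(layers) + 1L]] <- tibble::tibble(
    name = "fc2", type = if (spec$head == "conv1x1") "conv" else "dense",
    kernel = if (spec$head == "conv1x1") 1L else NA_integer_,
    in_ch = hidden, out_ch = 1L, stage = "head")
  structure(list(spec = spec, weights = weights,
                 layers = dplyr::bind_rows(layers)),
            class = "secondary_net")
}

secondary_forward <- function(net, x, training = FALSE) {
  spec <- net$spec
  w <- net$weights
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1L] != 64L || dim(x)[2L] != 64L) {
    stop("secondary network input must be 64x64")
  }
  pool_fwd <- if (spec$pooling == "average") avgpool2_forward else maxpool2_forward
  cache <- list(conv = vector("list", 5L), relu = vector("list", 5L),
                pool = vector("list", 3L))
  h <- x
  for (i in 1:5) {
    cv <- conv3x3_forward(h, w$conv[[i]]$W, w$conv[[i]]$b, training)
    rl <- relu_forward(cv$y)
    if (training) {
      cache$conv[[i]] <- cv$cache
      cache$relu[[i]] <- rl$cache
    }
    h <- rl$y
    if (i <= 3L) {
      pl <- pool_fwd(h)
      if (training) cache$pool[[i]] <- pl$cache
      h <- pl$y
    }
  }
  if (spec$head == "conv1x1") {
    gp <- gap_forward(h)
    feat <- gp$y
    cache$gap <- gp$cache
  } else {
    cache$flat_dims <- dim(h)
    feat <- array(h, c(1L, 1L, length(h)))
  }
  d1 <- dropout_forward(feat, spec$dropout_rate, training)
  f1 <- conv1x1_forward(d1$y, w$fc1$W, w$fc1$b)
  r1 <- relu_forward(f1$y)
  d2 <- dropout_forward(r1$y, spec$dropout_rate, training)
  f2 <- conv1x1_forward(d2$y, w$fc2$W, w$fc2$b)
  logit <- as.numeric(f2$y)
  if (training) {
    cache$d1 <- d1$cache; cache$f1 <- f1$cache; cache$r1 <- r1$cache
    cache$d2 <- d2$cache; cache$f2 <- f2$cache
  }
  list(score = sigmoid(logit), logit = logit, cache = cache)
}

secondary_backward <- function(net, cache, dlogit) {
  spec <- net$spec
  w <- net$weights
  g <- tree_zeros_like(w)
  pool_bwd <- if (spec$pooling == "average") avgpool2_backward else maxpool2_backward
  dl <- array(dlogit, c(1L, 1L, 1L))
  b2 <- conv1x1_backward(dl, cache$f2, w$fc2$W)
  g$fc2$W <- b2$dW; g$fc2$b <- b2$db
  dd2 <- dropout_backward(b2$dx, cache$d2)
  dr1 <- relu_backward(dd2, cache$r1)
  b1 <- conv1x1_backward(dr1, cache$f1, w$fc1$W)
  g$fc1$W <- b1$dW; g$fc1$b <- b1$db
  dfeat <- dropout_backward(b1$dx, cache$d1)
  dh <- if (spec$head == "conv1x1") gap_backward(dfeat, cache$gap)
        else array(dfeat, cache$flat_dims)
  for (i in 5:1) {
    if (i <= 3L) dh <- pool_bwd(dh, cache$pool[[i]])
    drl <- relu_backward(dh, cache$relu[[i]])
    cb <- conv3x3_backward(drl, cache$conv[[i]], w$conv[[i]]$W)
    g$conv[[i]]$W <- cb$dW; g$conv[[i]]$b <- cb$db
    dh <- cb$dx
  }
  g
}

#' Score ROIs with the secondary network
#'
#' Runs the secondary network in inference mode (dropout disabled) on one ROI
#' or a list of ROIs and returns P(LACI) for each, in input order.
#'
#' @param net A `secondary_net` (possibly trained; see [train_secondary()]).
#' @param rois A single 64x64 matrix, an [extract_roi()] result, or a list of
#'   either.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_secondary <- function(net, rois) {
  stopifnot(inherits(net, "secondary_net"))
  if (!is.list(rois) || inherits(rois, "roi_patch")) rois <- list(rois)
  vapply(rois, function(r) {
    px <- if (inherits(r, "roi_patch")) r$pixels else r
    secondary_forward(net, px, training = FALSE)$score
  }, numeric(1))
}

#' Count trainable parameters of a network
#'
#' @param net A `primary_net` or `secondary_net`.
#' @return Integer count of all trainable weights (conv kernels, biases and
#'   batch-norm scale/shift).
#' @export
n_parameters <- function(net) {
  total <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else total <<- total + length(x)
    invisible(NULL)
  }
  walk(net$weights)
  total
}

#' @export
print.primary_net <- function(x, ...) {
  cat("Primary segmentation network: depth", x$spec$depth,
      "| base channels", x$spec$base_channels,
      "| classes", x$spec$n_classes,
      "|", n_parameters(x), "parameters\n")
  invisible(x)
}

#' @export
print.secondary_net <- function(x, ...) {
  cat("Secondary correction network:", x$spec$pooling, "pooling |",
      x$spec$head, "head |", n_parameters(x), "parameters\n")
  invisible(x)
}
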