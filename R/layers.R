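# Vectorized forward/backward primitives for the two networks.
#
# Feature maps are numeric arrays H x W x C; a "layer" owns its parameters
# (a list of numeric arrays) and its cache for the backward pass. Convolution
# uses an im2col lowering so the inner loop is a single BLAS matmul; the
# backward col2im loops only over the 9*C kernel columns, never over pixels.

# ---- conv 3x3, stride 1, same (zero) padding -------------------------------

# W: (9*Cin) x Cout matrix, rows ordered (kernel offset outer, channel
# inner) so every kernel offset owns a contiguous block of C rows;
# b: length-Cout bias.

# im2col gather indices into the zero-padded array, cached per feature-map
# shape (they depend only on H, W, C).
.conv_idx_cache <- new.env(parent = emptyenv())

conv3x3_indices <- function(H, Wd, C) {
  key <- paste(H, Wd, C, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L
  plane <- Hp * (Wd + 2L)
  # linear index of padded pixel (r + di, c + dj) in channel ch
  base_r <- rep.int(seq_len(H), Wd)
  base_c <- rep(seq_len(Wd), each = H)
  idx <- vector("list", 9L * C)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      off <- (base_c + dj - 1L) * Hp + base_r + di
      for (ch in seq_len(C)) {
        k <- k + 1L
        idx[[k]] <- off + (ch - 1L) * plane
      }
    }
  }
  out <- unlist(idx, use.names = FALSE)
  .conv_idx_cache[[key]] <- out
  out
}

conv3x3_forward <- function(x, W, b, want_cache = TRUE) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  xp <- array(0, c(H + 2L, Wd + 2L, C))
  xp[2:(H + 1L), 2:(Wd + 1L), ] <- x
  idx <- conv3x3_indices(H, Wd, C)
  M <- xp[idx]
  dim(M) <- c(H * Wd, 9L * C)
  out <- M %*% W
  out <- out + rep(b, each = H * Wd)
  list(y = array(out, c(H, Wd, ncol(W))),
       cache = if (want_cache) list(M = M, dims = c(H, Wd, C)) else NULL)
}

conv3x3_backward <- function(dy, cache, W, want_dx = TRUE) {
  H <- cache$dims[1L]; Wd <- cache$dims[2L]; C <- cache$dims[3L]
  n <- H * Wd
  dyM <- dy
  dim(dyM) <- c(n, ncol(W))
  dW <- crossprod(cache$M, dyM)
  db <- colSums(dyM)
  if (!want_dx) return(list(dx = NULL, dW = dW, db = db))
  dM <- tcrossprod(dyM, W)
  idx <- conv3x3_indices(H, Wd, C)
  dxp <- numeric((H + 2L) * (Wd + 2L) * C)
  blk <- n * C # one kernel offset = C contiguous columns = n*C entries
  for (o in 0:8) {
    ii <- idx[(o * blk + 1L):((o + 1L) * blk)]
    dxp[ii] <- dxp[ii] + dM[(o * blk + 1L):((o + 1L) * blk)]
  }
  dim(dxp) <- c(H + 2L, Wd + 2L, C)
  list(dx = dxp[2:(H + 1L), 2:(Wd + 1L), , drop = FALSE], dW = dW, db = db)
}

# ---- conv 1x1 --------------------------------------------------------------

conv1x1_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  out <- xm %*% W
  out <- out + rep(b, each = nrow(xm))
  list(y = array(out, c(d[1L], d[2L], ncol(W))), cache = list(xm = xm, dims = d))
}

conv1x1_backward <- function(dy, cache, W) {
  d <- cache$dims
  dyM <- matrix(dy, d[1L] * d[2L], ncol(W))
  list(dx = array(tcrossprod(dyM, W), d),
       dW = crossprod(cache$xm, dyM),
       db = colSums(dyM))
}

# ---- ReLU ------------------------------------------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

# ---- batch normalization (per channel over the spatial grid) ---------------

# Single-sample spatial statistics during training (gradients are accumulated
# across a mini-batch outside); running mean/var used at inference.
bn_forward <- function(x, gamma, beta, running, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n <- d[1L] * d[2L]
  xm <- x
  dim(xm) <- c(n, d[3L])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  # y = xm * (inv*gamma) + (beta - mu*inv*gamma), fused per channel
  a <- inv * gamma
  y <- xm * rep(a, each = n) + rep(beta - mu * a, each = n)
  list(y = array(y, d), running = running,
       cache = list(xm = xm, mu = mu, inv = inv, n = n, dims = d,
                    gamma = gamma))
}

bn_backward <- function(dy, cache) {
  n <- cache$n
  d <- cache$dims
  dyM <- dy
  dim(dyM) <- c(n, d[3L])
  xhat <- (cache$xm - rep(cache$mu, each = n)) * rep(cache$inv, each = n)
  dgamma <- colSums(dyM * xhat)
  dbeta <- colSums(dyM)
  dxhat <- dyM * rep(cache$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(cache$inv, each = n)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

bn_init_running <- function(n_channels) {
  list(mean = numeric(n_channels), var = rep(1, n_channels))
}

# ---- 2x2 pooling, stride 2 -------------------------------------------------

pool_views <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1L], 2L); ci <- seq(1L, d[2L], 2L)
  list(x[ri, ci, , drop = FALSE], x[ri + 1L, ci, , drop = FALSE],
       x[ri, ci + 1L, , drop = FALSE], x[ri + 1L, ci + 1L, , drop = FALSE])
}

maxpool2_forward <- function(x) {
  v <- pool_views(x)
  y <- v[[1L]]
  idx <- array(1L, dim(y))
  for (k in 2:4) {
    w <- v[[k]] > y
    y[w] <- v[[k]][w]
    idx[w] <- k
  }
  list(y = y, cache = list(idx = idx, dims = dim(x)))
}

maxpool2_backward <- function(dy, cache) {
  dx <- array(0, cache$dims)
  ri <- seq(1L, cache$dims[1L], 2L); ci <- seq(1L, cache$dims[2L], 2L)
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    m <- cache$idx == k
    sub <- dx[ri + off[[k]][1L], ci + off[[k]][2L], , drop = FALSE]
    sub[m] <- dy[m]
    dx[ri + off[[k]][1L], ci + off[[k]][2L], ] <- sub
  }
  dx
}

avgpool2_forward <- function(x) {
  v <- pool_views(x)
  list(y = (v[[1L]] + v[[2L]] + v[[3L]] + v[[4L]]) / 4, cache = list(dims = dim(x)))
}

avgpool2_backward <- function(dy, cache) {
  dx <- array(0, cache$dims)
  ri <- seq(1L, cache$dims[1L], 2L); ci <- seq(1L, cache$dims[2L], 2L)
  q <- dy / 4
  for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
    dx[ri + off[1L], ci + off[2L], ] <- q
  }
  dx
}

# ---- 2x2 stride-2 transposed convolution (upsampling "deconvolution") ------

# W: array Cin x Cout x 4, position k covering output offset
# (di, dj) = ((k-1) %% 2, (k-1) %/% 2); b: length-Cout bias.
upconv2_forward <- function(x, W, b) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]
  cout <- dim(W)[2L]
  xm <- matrix(x, H * Wd, d[3L])
  y <- array(rep(b, each = 4L * H * Wd), c(2L * H, 2L * Wd, cout))
  for (k in 1:4) {
    di <- (k - 1L) %% 2L; dj <- (k - 1L) %/% 2L
    y[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * Wd, 2L), ] <-
      y[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * Wd, 2L), , drop = FALSE] +
      array(xm %*% W[, , k], c(H, Wd, cout))
  }
  list(y = y, cache = list(xm = xm, dims = d))
}

upconv2_backward <- function(dy, cache, W) {
  d <- cache$dims
  H <- d[1L]; Wd <- d[2L]
  cout <- dim(W)[2L]
  dW <- array(0, dim(W))
  dxm <- matrix(0, H * Wd, d[3L])
  db <- numeric(cout)
  for (k in 1:4) {
    di <- (k - 1L) %% 2L; dj <- (k - 1L) %/% 2L
    dyk <- matrix(dy[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * Wd, 2L), ,
                     drop = FALSE], H * Wd, cout)
    dW[, , k] <- crossprod(cache$xm, dyk)
    dxm <- dxm + tcrossprod(dyk, W[, , k])
    db <- db + colSums(dyk)
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

# ---- heads -----------------------------------------------------------------

# Softmax over the channel dimension; returns H x W x K array of probabilities.
softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1L] * d[2L], d[3L])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Global average pool H x W x C -> 1 x 1 x C.
gap_forward <- function(x) {
  d <- dim(x)
  list(y = array(colMeans(matrix(x, d[1L] * d[2L], d[3L])), c(1L, 1L, d[3L])),
       cache = d)
}

gap_backward <- function(dy, cache) {
  n <- cache[1L] * cache[2L]
  array(rep(as.vector(dy) / n, each = n), cache)
}

# Inverted dropout; mask drawn from the current RNG stream.
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - rate
  mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim(x))
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- parameter-tree utilities ---------------------------------------------

# Weights/gradients/optimizer accumulators share one nested-list shape; these
# helpers walk two trees in lockstep.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

tree_zeros_like <- function(a) tree_map(a, function(x) x * 0)

tree_add <- function(a, b) tree_map2(a, b, `+`)

tree_scale <- function(a, s) tree_map(a, function(x) x * s)

he_init <- function(n_out_shape, fan_in) {
  array(stats::rnorm(prod(n_out_shape), sd = sqrt(2 / fan_in)), n_out_shape)
}
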