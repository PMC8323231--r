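# Independent brute-force oracles used to validate the package's
# vectorized implementations.

# recursive flood fill labelling (stack-based), the reference for
# extract_components
flood_fill_label <- function(mask, connectivity = 8L) {
  fg <- mask > 0
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  cur <- 0L
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      if (fg[r, cc] && lab[r, cc] == 0L) {
        cur <- cur + 1L
        stack <- list(c(r, cc))
        lab[r, cc] <- cur
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (k in seq_len(nrow(nb))) {
            rr <- p[1] + nb[k, 1]; ccn <- p[2] + nb[k, 2]
            if (rr >= 1 && rr <= H && ccn >= 1 && ccn <= W &&
                fg[rr, ccn] && lab[rr, ccn] == 0L) {
              lab[rr, ccn] <- cur
              stack[[length(stack) + 1L]] <- c(rr, ccn)
            }
          }
        }
      }
    }
  }
  lab
}

# sorted numeric pixel keys of an (row, col) pixel matrix
keys_of <- function(px) sort(as.numeric(px[, 1] * 1e6 + px[, 2]))

# canonical partition of a labelled image: list of sorted pixel-key vectors,
# ordered lexicographically (independent of label numbering)
partition_of <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  parts <- lapply(ids, function(i) {
    sort(as.numeric(row(lab)[lab == i] * 1e6 + col(lab)[lab == i]))
  })
  parts[order(vapply(parts, min, numeric(1)))]
}

# exhaustive optimal one-to-one assignment: maximum number of matched pairs
# with IoU strictly above the threshold (reference for greedy matching
# counts when instance lists are small)
best_assignment_count <- function(iou_mat, thr) {
  np <- nrow(iou_mat); nt <- ncol(iou_mat)
  if (np == 0L || nt == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1L) <= best && i <= np) {
      # prune: cannot beat current best
    }
    if (i > np) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count) # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && iou_mat[i, j] > thr) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt), 0L)
  best
}

# random small binary mask with a few blobs
random_small_mask <- function(H = 10L, W = 10L, p = 0.3) {
  matrix(stats::rbinom(H * W, 1L, p), H, W)
}

# tiny network/training fixtures shared across tests
tiny_primary_spec <- function(n_classes = 2L) {
  primary_net_spec(depth = 2L, base_channels = 2L, n_classes = n_classes,
                   input_size = 16L)
}

tiny_phantom_config <- function(image_size = 64L,
                                lesion_count_range = c(1L, 6L), ...) {
  phantom_config(image_size = image_size,
                 lesion_count_range = lesion_count_range, noise_sd = 0, ...)
}
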