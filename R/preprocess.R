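#' Gamma intensity transform
#'
#' Pixelwise power-law mapping `out = in^gamma` on normalized intensities.
#' With `gamma > 1` low intensities are compressed relative to high ones,
#' which stretches the bright end of small low-contrast patches; the default
#' exponent used for secondary-network ROIs is 1.5.
#'
#' @param image Numeric matrix/array with all values in `[0, 1]`.
#' @param gamma Positive exponent.
#' @return Transformed image, same shape, values in `[0, 1]`.
#' @examples
#' gamma_transform(matrix(0.25), 1.5) # 0.125
#' @export
gamma_transform <- function(image, gamma = 1.5) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("`gamma` must be a positive scalar")
  }
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 1) {
    stop("`image` values must be finite and in [0, 1]")
  }
  image^gamma
}

#' Min-max normalize a patch to [0, 1]
#'
#' @param raw_patch Nonempty numeric matrix.
#' @return The patch scaled so its minimum maps to 0 and its maximum to 1;
#'   a constant patch maps to all zeros by convention.
#' @export
normalize_roi <- function(raw_patch) {
  if (length(raw_patch) == 0L) stop("patch is empty")
  rng <- range(raw_patch)
  if (rng[1L] == rng[2L]) return(raw_patch * 0)
  (raw_patch - rng[1L]) / (rng[2L] - rng[1L])
}

# Separable image resize by pixel-center mapping.
resize_grid <- function(img, out_rows, out_cols = out_rows,
                        method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  # pixel-center mapping (1-based): src = (i - 0.5) * scale + 0.5
  src_r <- (seq_len(out_rows) - 0.5) * H / out_rows + 0.5
  src_c <- (seq_len(out_cols) - 0.5) * W / out_cols + 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(floor(src_r + 0.5), 1L), H)
    ci <- pmin(pmax(floor(src_c + 0.5), 1L), W)
    return(img[ri, ci, drop = FALSE])
  }
  r0 <- pmin(pmax(floor(src_r), 1L), H)
  r1 <- pmin(r0 + 1L, H)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  c0 <- pmin(pmax(floor(src_c), 1L), W)
  c1 <- pmin(c0 + 1L, W)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  top <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    img[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    img[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

round_half_up <- function(x) floor(x + 0.5)

#' Extract a secondary-network ROI around a lesion centroid
#'
#' Crops a `crop_size` x `crop_size` window centred on the rounded centroid
#' (zero-padded where the window exits the image), upsamples it to
#' `out_size` x `out_size`, then min-max normalizes and applies the gamma
#' transform, in that order.
#'
#' @param t1 T1 intensity matrix in `[0, 1]`.
#' @param centroid Real-valued `(row, col)`; rounded half-away-from-zero to
#'   the nearest pixel. Must lie within the image.
#' @param crop_size Window side before upsampling (default 32).
#' @param out_size Output side (default 64).
#' @param gamma Gamma exponent applied after normalization (default 1.5).
#' @param interp `"bilinear"` (default) or `"nearest"` upsampling.
#' @param slice_id,true_class Optional provenance stored on the patch.
#' @return An object of class `roi_patch`: `pixels` (out_size x out_size in
#'   `[0, 1]`), `source_centroid`, `source_slice_id`, `true_class`.
#' @export
extract_roi <- function(t1, centroid, crop_size = 32L, out_size = 64L,
                        gamma = 1.5, interp = c("bilinear", "nearest"),
                        slice_id = NA_character_, true_class = NULL) {
  interp <- match.arg(interp)
  H <- nrow(t1); W <- ncol(t1)
  rc <- round_half_up(centroid[1L])
  cc <- round_half_up(centroid[2L])
  if (rc < 1L || rc > H || cc < 1L || cc > W) {
    stop("centroid lies outside the image")
  }
  half <- crop_size %/% 2L
  r_lo <- rc - half + 1L
  c_lo <- cc - half + 1L
  crop <- matrix(0, crop_size, crop_size)
  rr <- r_lo:(r_lo + crop_size - 1L)
  cs <- c_lo:(c_lo + crop_size - 1L)
  rin <- rr >= 1L & rr <= H
  cin <- cs >= 1L & cs <= W
  crop[rin, cin] <- t1[rr[rin], cs[cin], drop = FALSE]
  up <- resize_grid(crop, out_size, out_size, method = interp)
  out <- gamma_transform(normalize_roi(up), gamma)
  structure(list(pixels = out,
                 source_centroid = c(centroid[1L], centroid[2L]),
                 source_slice_id = slice_id,
                 true_class = true_class),
            class = "roi_patch")
}

# inverse-mapping rotation about the image center; bilinear or nearest.
rotate_grid <- function(img, angle_deg, method = c("bilinear", "nearest"),
                        fill = 0) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  ctr_r <- (H + 1) / 2; ctr_c <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W) - ctr_r
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr_c
  # rotate sampling coordinates by -angle (inverse map)
  src_r <- cos(th) * rows + sin(th) * cols + ctr_r
  src_c <- -sin(th) * rows + cos(th) * cols + ctr_c
  out <- matrix(fill, H, W)
  if (method == "nearest") {
    ri <- round_half_up(src_r)
    ci <- round_half_up(src_c)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    idx <- function(dr, dc) img[cbind(r0[ok] + dr, c0[ok] + dc)]
    out[ok] <- idx(0, 0) * (1 - fr[ok]) * (1 - fc[ok]) +
      idx(0, 1) * (1 - fr[ok]) * fc[ok] +
      idx(1, 0) * fr[ok] * (1 - fc[ok]) +
      idx(1, 1) * fr[ok] * fc[ok]
  }
  out
}

check_rotation_angles <- function(angles) {
  a <- abs(angles)
  if (any(a < 5 | a > 10)) {
    stop("rotation angles must lie in [5, 10] or [-10, -5] degrees")
  }
  invisible(angles)
}

#' Rotation augmentation of a slice pair and its mask
#'
#' Produces one rotated copy per requested angle. Angles are restricted to
#' small rotations of 5--10 degrees clockwise or counterclockwise (negative
#' = clockwise). Images are rotated with bilinear interpolation, masks with
#' nearest-neighbour so labels stay in \{0, 1, 2\}; regions rotated in from
#' outside the frame are filled with 0.
#'
#' @param pair A `slice_pair`.
#' @param mask The matching integer label mask.
#' @param angles_degrees Numeric vector of angles in
#'   `[5, 10]` or `[-10, -5]`.
#' @return A list with one element per angle, each a list with `pair`,
#'   `mask`, and `angle`.
#' @export
augment_rotations <- function(pair, mask, angles_degrees) {
  stopifnot(inherits(pair, "slice_pair"))
  check_rotation_angles(angles_degrees)
  purrr::map(angles_degrees, function(a) {
    t2r <- pmin(pmax(rotate_grid(pair$t2, a, "bilinear"), 0), 1)
    t1r <- pmin(pmax(rotate_grid(pair$t1, a, "bilinear"), 0), 1)
    mr <- rotate_grid(mask, a, "nearest")
    storage.mode(mr) <- "integer"
    list(pair = new_slice_pair(t2r, t1r, pair$patient_id,
                               paste0(pair$slice_id, "_rot", a)),
         mask = mr,
         angle = a)
  })
}

#' Build the two-phase oversampling schedule
#'
#' Slices containing many tiny lesions are scarce but carry most of the
#' foreground signal; phase 1 pre-trains on exactly those (lesion count
#' strictly greater than `threshold`), phase 2 uses all training slices.
#'
#' @param lesion_counts Nonnegative integer vector, one count per training
#'   slice.
#' @param threshold Lesion count above which a slice enters phase 1
#'   (default 5, echoing the "more than 5" lesion-rich selection rule).
#' @return An object of class `oversample_schedule` with `phase1_indices`,
#'   `phase2_indices` and `lesion_count_threshold`.
#' @examples
#' build_oversample_schedule(c(3, 6, 7, 0))
#' @export
build_oversample_schedule <- function(lesion_counts, threshold = 5L) {
  if (any(lesion_counts < 0)) stop("lesion counts must be nonnegative")
  phase1 <- which(lesion_counts > threshold)
  if (length(phase1) == 0L) {
    stop("no slice has more than ", threshold,
         " lesions; lower `threshold` to enable oversampling")
  }
  structure(list(phase1_indices = phase1,
                 phase2_indices = seq_along(lesion_counts),
                 lesion_count_threshold = as.integer(threshold)),
            class = "oversample_schedule")
}

# trivial schedule for single-phase training (no oversampling ablation)
single_phase_schedule <- function(n) {
  structure(list(phase1_indices = seq_len(n), phase2_indices = seq_len(n),
                 lesion_count_threshold = NA_integer_),
            class = "oversample_schedule")
}
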