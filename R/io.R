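#' Read a co-registered T2/T1 slice pair from files
#'
#' Accepts 8/16-bit grayscale PNG or single-slice NIfTI (`.nii`/`.nii.gz`,
#' requires the RNifti package). Each image is min-max scaled to `[0, 1]`;
#' the two images must have identical shapes and a single channel.
#'
#' @param t2_path,t1_path File paths.
#' @param patient_id,slice_id Identifiers stored on the pair.
#' @return A `slice_pair`.
#' @export
read_slice_pair <- function(t2_path, t1_path, patient_id = NA_character_,
                            slice_id = NA_character_) {
  t2 <- read_intensity_image(t2_path)
  t1 <- read_intensity_image(t1_path)
  if (!identical(dim(t2), dim(t1))) {
    stop("T2 and T1 images have different shapes")
  }
  new_slice_pair(t2, t1, patient_id, slice_id)
}

read_intensity_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package")
    }
    v <- RNifti::readNifti(path)
    a <- as.array(v)
    if (length(dim(a)) == 3L && dim(a)[3L] == 1L) a <- a[, , 1L]
    matrix(as.numeric(a), nrow(a), ncol(a)) # plain matrix, no NIfTI attrs
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L) stop("multi-channel image: ", path)
    img <- img[, , 1L]
  }
  rng <- range(img)
  if (rng[1L] == rng[2L]) return(img * 0)
  (img - rng[1L]) / (rng[2L] - rng[1L])
}

#' Write a semantic label mask as an 8-bit PNG
#'
#' Values must be in \{0, 1, 2\}; the file round-trips losslessly through
#' [read_semantic_mask()].
#'
#' @param mask Integer matrix in \{0, 1, 2\}.
#' @param path Output path (`.png`).
#' @export
write_semantic_mask <- function(mask, path) {
  if (!all(mask %in% c(0L, 1L, 2L))) {
    stop("mask values must be in {0, 1, 2}")
  }
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a semantic label mask written by [write_semantic_mask()]
#'
#' @param path PNG path.
#' @return Integer matrix in \{0, 1, 2\}.
#' @export
read_semantic_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- round(m * 255)
  storage.mode(out) <- "integer"
  if (!all(out %in% c(0L, 1L, 2L))) {
    stop("file does not contain a {0, 1, 2} label mask")
  }
  out
}

#' Write a phantom dataset to disk with a manifest
#'
#' Writes per-slice images (`.nii.gz` float by default for losslessness, or
#' 8-bit `.png`), 8-bit PNG label masks, and an `index.csv` manifest with
#' columns `patient_id`, `slice_id`, `t2_path`, `t1_path`, `mask_path`.
#'
#' @param dataset A dataset tibble (see [generate_dataset()]).
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` (default) or `"png"`.
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  if (format == "nifti" && !requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  rows <- purrr::map(seq_len(nrow(dataset)), function(i) {
    sid <- dataset$slice_id[i]
    t2_path <- file.path(dir, paste0(sid, "_t2", ext))
    t1_path <- file.path(dir, paste0(sid, "_t1", ext))
    mask_path <- file.path(dir, paste0(sid, "_mask.png"))
    if (format == "nifti") {
      RNifti::writeNifti(RNifti::asNifti(dataset$t2[[i]]), t2_path)
      RNifti::writeNifti(RNifti::asNifti(dataset$t1[[i]]), t1_path)
    } else {
      png::writePNG(dataset$t2[[i]], t2_path)
      png::writePNG(dataset$t1[[i]], t1_path)
    }
    write_semantic_mask(dataset$mask[[i]], mask_path)
    tibble::tibble(patient_id = dataset$patient_id[i], slice_id = sid,
                   t2_path = basename(t2_path), t1_path = basename(t1_path),
                   mask_path = basename(mask_path))
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `index.csv` and the image files.
#' @return A dataset tibble with the same columns as [generate_dataset()]
#'   (instances derived from the masks).
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "index.csv"),
                              stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    pair <- read_slice_pair(file.path(dir, manifest$t2_path[i]),
                            file.path(dir, manifest$t1_path[i]),
                            manifest$patient_id[i], manifest$slice_id[i])
    mask <- read_semantic_mask(file.path(dir, manifest$mask_path[i]))
    inst <- extract_components(mask > 0L)
    if (nrow(inst) > 0L) {
      inst$class <- vapply(seq_len(nrow(inst)), function(k) {
        majority_class(mask, inst$pixels[[k]])
      }, character(1))
    } else {
      inst$class <- character()
    }
    tibble::tibble(patient_id = manifest$patient_id[i],
                   slice_id = manifest$slice_id[i],
                   healthy = nrow(inst) == 0L,
                   t2 = list(pair$t2), t1 = list(pair$t1), mask = list(mask),
                   instances = list(inst), n_lesions = nrow(inst))
  })
  dplyr::bind_rows(rows)
}

#' Read and validate a YAML run configuration
#'
#' A single human-readable document with optional sections `phantom`,
#' `train`, `eval`, `primary`, `secondary`; each key must belong to the
#' corresponding constructor's arguments (unknown keys are rejected) and
#' every component's invariants are validated on load.
#'
#' @param path YAML file path.
#' @return A list with validated `phantom` ([phantom_config()]), `train`
#'   ([train_config()]), `eval` ([eval_config()]), `primary`
#'   ([primary_net_spec()]) and `secondary` ([secondary_net_spec()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_sections <- c("phantom", "train", "eval", "primary", "secondary")
  extra <- setdiff(names(raw), known_sections)
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  builders <- list(phantom = phantom_config, train = train_config,
                   eval = eval_config, primary = primary_net_spec,
                   secondary = secondary_net_spec)
  out <- list()
  for (sec in known_sections) {
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(builders[[sec]])))
    if (length(bad)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
    out[[sec]] <- do.call(builders[[sec]], args)
  }
  out
}
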