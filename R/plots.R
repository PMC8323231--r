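#' Plot a slice pair with optional mask overlay
#'
#' Shows the T2 and T1 images side by side; when a label mask is supplied,
#' lesion pixels are outlined by class (FCI, LACI).
#'
#' @param pair A `slice_pair`.
#' @param mask Optional integer mask in \{0, 1, 2\}.
#' @return A ggplot object.
#' @export
plot_slice_pair <- function(pair, mask = NULL) {
  stopifnot(inherits(pair, "slice_pair"))
  long <- function(m, which) {
    tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                   intensity = as.vector(m), modality = which)
  }
  df <- dplyr::bind_rows(long(pair$t2, "T2 FLAIR"), long(pair$t1, "T1 FLAIR"))
  df$modality <- factor(df$modality, c("T2 FLAIR", "T1 FLAIR"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity",
                  title = paste("Slice", pair$slice_id)) +
    ggplot2::theme_void()
  if (!is.null(mask) && any(mask > 0L)) {
    md <- tibble::tibble(row = as.vector(row(mask)), col = as.vector(col(mask)),
                         label = as.vector(mask))
    md <- md[md$label > 0L, ]
    md$class <- c("FCI", "LACI")[md$label]
    p <- p + ggplot2::geom_point(
      data = md, ggplot2::aes(.data$col, -.data$row, colour = .data$class),
      inherit.aes = FALSE, shape = 0, size = 0.8, stroke = 0.4) +
      ggplot2::scale_colour_manual(values = c(FCI = "#00BFC4",
                                              LACI = "#F8766D"))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-fold cross-validation metrics
#'
#' One point per fold and metric, with the fold mean marked.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$folds[, c("fold", "dice", "detection_precision",
                     "classification_precision")],
    -"fold", names_to = "metric", values_to = "value")
  means <- dplyr::summarise(dplyr::group_by(df, .data$metric),
                            value = mean(.data$value, na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::geom_point(data = means, shape = 95, size = 10) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = "fold",
                  title = "Cross-validation metrics (bar = fold mean)") +
    ggplot2::theme_minimal()
}

#' Plot training loss history
#'
#' @param fit A `primary_fit` or `secondary_fit`.
#' @return A ggplot object showing per-epoch loss by phase.
#' @export
plot_history <- function(fit) {
  h <- fit$history
  h$step <- seq_len(nrow(h))
  ggplot2::ggplot(h, ggplot2::aes(.data$step, .data$loss,
                                  colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch (phases concatenated)", y = "mean loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}
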