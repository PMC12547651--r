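#' Plot methods for pipeline results
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' the labeling histogram (treated delta-MFR coloured by label, with the
#' untreated null overlaid), the ROC curve of a holdout report, the
#' per-model cross-validated AUC distribution, and the two-component PCA
#' projection.
#'
#' @param object A `noci_labels` tibble, `classifier_report`, `cv_result`,
#'   or `pca_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-nocilabel
NULL

#' @rdname autoplot-nocilabel
#' @param untreated_deltas Optional numeric vector (or delta tibble) of
#'   untreated deltas to overlay as the null distribution.
#' @export
autoplot.noci_labels <- function(object, untreated_deltas = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$delta_mfr_hz,
                                    fill = .data$label)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8, position = "identity") +
    ggplot2::scale_fill_manual(values = c(nociceptor = "#c0392b",
                                          `non-nociceptor` = "#f1c40f")) +
    ggplot2::labs(x = expression(Delta * "MFR (Hz, max-bin)"),
                  y = "units", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(untreated_deltas)) {
    ud <- as_delta_table(untreated_deltas, "untreated")
    p <- p + ggplot2::geom_histogram(
      data = ud, ggplot2::aes(x = .data$delta_mfr_hz),
      bins = 60, fill = "#2980b9", alpha = 0.4, inherit.aes = FALSE)
  }
  p
}

#' @rdname autoplot-nocilabel
#' @export
autoplot.classifier_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c3e50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC-ROC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nocilabel
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "fold AUC-ROC") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nocilabel
#' @export
autoplot.pca_projection <- function(object, ...) {
  train <- dplyr::mutate(object$train, set = "train")
  d <- if (!is.null(object$test)) {
    dplyr::bind_rows(train, dplyr::mutate(object$test, set = "test"))
  } else train
  aes <- if ("label" %in% names(d)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$label,
                 shape = .data$set)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, shape = .data$set)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nocilabel
#' @export
plot_confidence_curve <- function(object, ...) {
  curve <- if (inherits(object, "classifier_report")) {
    object$confidence_curve
  } else tibble::as_tibble(object)
  curve |>
    tidyr::pivot_longer(c("accuracy", "retention"), names_to = "series") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$confidence, y = .data$value,
                                 colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "confidence cutoff", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
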