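#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bias audit as a dot chart of dc by variable and subset
#'
#' @param object A [bias_audit()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_audit
#' @export
autoplot.bias_audit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dc, y = .data$variable,
      colour = .data$subset, shape = .data$interaction_flag)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
      name = "interaction flag") +
    ggplot2::labs(x = "squared distance correlation with features",
      y = NULL, colour = "cohort subset") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the per-iteration dc trace of a trained model
#'
#' Mirrors the training-time monitoring view: the dependence of the learned
#' features on the target should rise while, under ablation, the dependence
#' on each bias stays low.
#'
#' @param object An `msi_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msi_model
#' @export
autoplot.msi_model <- function(object, ...) {
  long <- tidy.msi_model(object)
  long <- dplyr::filter(long, startsWith(.data$metric, "dc_"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
      colour = .data$metric)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
      linewidth = 0.8) +
    ggplot2::labs(x = "batch iteration",
      y = "squared distance correlation with features",
      colour = NULL,
      title = if (object$ablate) "bias-ablated training" else "baseline training") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D PCA projection coloured by a protected variable
#'
#' @param object A [pca_projection()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_projection
#' @export
autoplot.pca_projection <- function(object, ...) {
  expl <- attr(object, "explained")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("color" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$color),
      alpha = 0.7) + ggplot2::labs(colour = NULL)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * expl[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * expl[min(2, length(expl))])) +
    ggplot2::theme_minimal()
}

#' Bar chart of stratified false positive / negative rates
#'
#' @param rates Output of [stratified_error_rates()].
#' @return A ggplot object.
#' @export
plot_error_rates <- function(rates) {
  long <- tidyr::pivot_longer(rates[, c("stratum", "level", "fpr", "fnr")],
    cols = c("fpr", "fnr"), names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
      fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stratum, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "rate", fill = NULL) +
    ggplot2::theme_minimal()
}
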