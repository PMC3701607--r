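# ggplot2 figures for the result objects.

#' Histogram-with-rug exceedance figure
#'
#' Nontoxin null histogram with the percentile threshold as a vertical
#' line and toxin values as a rug beneath, exceedances highlighted.
#'
#' @param object an `exceedance_report`
#' @param bins histogram bins
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.exceedance_report <- function(object, bins = 40, ...) {
  null_df <- tibble::tibble(value = object$nontoxin_values)
  tox_df <- object$toxin_values
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::geom_rug(data = tox_df,
                      ggplot2::aes(x = .data$value, colour = .data$exceeds),
                      sides = "b", linewidth = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 name = "exceeds 95th pct.") +
    ggplot2::labs(
      x = object$statistic, y = "nontoxin pairs",
      title = sprintf("%s: %d of %d toxins exceed (expected %.3g)",
                      object$statistic, object$observed, object$n_toxins,
                      object$expected)) +
    ggplot2::theme_minimal()
}

#' Cross-species expression scatter with fits
#'
#' @param object an `xspecies_regression`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.xspecies_regression <- function(object, ...) {
  d <- object$data
  d$removed <- d$id %in% object$removed
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$removed), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_abline(slope = stats::coef(object$full)[2],
                         intercept = stats::coef(object$full)[1],
                         colour = "grey50") +
    ggplot2::labs(x = "species A reads", y = "species B reads") +
    ggplot2::theme_minimal()
  if (!is.null(object$refit)) {
    p <- p + ggplot2::geom_abline(slope = stats::coef(object$refit)[2],
                                  intercept = stats::coef(object$refit)[1],
                                  colour = "blue")
  }
  p
}

#' Toxin-class expression bars
#'
#' @param class_summary tibble from [summarize_toxin_classes()]
#' @return a ggplot
#' @export
plot_class_summary <- function(class_summary) {
  d <- dplyr::mutate(class_summary,
                     class = stats::reorder(.data$class, -.data$pct_toxin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$pct_toxin)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of toxin reads") +
    ggplot2::theme_minimal()
}
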