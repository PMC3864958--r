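# ggplot2 displays for the main result types.

#' Plot an assignment-accuracy curve
#'
#' Percent correctly assigned against panel size (independent alleles),
#' optionally overlaid with the exponential fit.
#'
#' @param object An `accuracy_curve` tibble.
#' @param fit Optional `marker_fit` to overlay as a dashed curve.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$independent_alleles,
                                            y = .data$overall_pct)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Independent alleles in panel",
                  y = "Correct assignment (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      independent_alleles = seq(min(object$independent_alleles),
                                max(object$independent_alleles),
                                length.out = 200))
    grid$overall_pct <- exp(fit$a + fit$b / grid$independent_alleles)
    p <- p + ggplot2::geom_line(data = grid, linetype = "dashed",
                                colour = "firebrick")
  }
  p
}

#' Plot an outlier scan
#'
#' BayeScan-style display: posterior mean locus F_ST against log10 posterior
#' odds of selection, with the decision thresholds marked and selected loci
#' highlighted.
#'
#' @param object An `outlier_scan` tibble.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.outlier_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log10_po, y = .data$fst,
                                       colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 name = "Selected") +
    ggplot2::labs(x = expression(log[10] ~ "posterior odds"),
                  y = expression(F[ST])) +
    ggplot2::theme_minimal()
}

#' Plot per-locus divergence distributions
#'
#' Boxplots of the divergence scores with the upper-quartile threshold that
#' classifies high-differentiation loci.
#'
#' @param divergence Tibble from [locus_divergence()].
#'
#' @return A ggplot object.
#' @export
plot_divergence <- function(divergence) {
  long <- tidyr::pivot_longer(divergence, -"locus", names_to = "score",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Divergence score") +
    ggplot2::theme_minimal()
}
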