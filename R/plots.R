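#' Plot a joint posterior of the reciprocal migration rates
#'
#' Heatmap of the grid posterior with the neutral estimate marked when
#' supplied.
#'
#' @param object An `lsd_posterior`.
#' @param estimate Optional `lsd_neutral_estimate`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.lsd_posterior <- function(object, estimate = NULL, ...) {
  g <- object$grid
  df <- tidyr::expand_grid(a2 = g$axis2, a1 = g$axis1)
  df <- dplyr::arrange(df, .data$a2, .data$a1)
  df$mass <- as.vector(object$mass)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$a1, .data$a2, fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = paste0("log10 ", g$names[1]),
                  y = paste0("log10 ", g$names[2]), fill = "mass") +
    ggplot2::theme_minimal()
  if (!is.null(estimate)) {
    p <- p + ggplot2::annotate("point", x = estimate$value[1],
                               y = estimate$value[2], colour = "red", size = 2)
  }
  p
}

#' Manhattan-style plot of scan p-values
#'
#' Loci are laid out consecutively on a pseudo-chromosome; the dashed line
#' marks the significance threshold (posterior-probability scale, e.g.
#' 0.001 for a 99.9% credibility cutoff).
#'
#' @param object An `lsd_scan`.
#' @param threshold Significance line on the p scale.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.lsd_scan <- function(object, threshold = 0.001, ...) {
  df <- object$records
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, -log10(pmax(.data$p, 1e-6)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$a), size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey60", high = "red",
                                    midpoint = 0) +
    ggplot2::labs(x = "locus", y = expression(-log[10](p[l])),
                  colour = "asymmetry a") +
    ggplot2::theme_minimal()
}

#' Plot an ROC staircase
#'
#' @param object An `lsd_roc` from [roc_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.lsd_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
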