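#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a score or baseline regression
#'
#' Scatter of percentage improvement against the predictor with the fitted
#' least-squares line and an annotation of r, R-squared and the slope
#' p-value.
#'
#' @param object A `tgs_regression` from [score_regression()] or
#'   [baseline_regression()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tgs_regression
#' @export
autoplot.tgs_regression <- function(object, ...) {
  df <- object$data
  xvar <- setdiff(names(df), c("participant_id", "pct_change"))[1]
  lab <- sprintf("r = %.2f, R² = %.2f, p = %.2g",
                 object$r, object$r2, object$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$pct_change)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = object$predictor,
                  y = "Cooper run improvement (%)") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of individual training responses
#'
#' One bar per training-arm participant, ordered by percentage
#' improvement, with the arm mean as a dashed reference line — the
#' standard display of inter-individual response heterogeneity.
#'
#' @param responses Tibble from [cooper_responses()] (training-arm rows
#'   are used).
#' @return A ggplot.
#' @export
plot_response_waterfall <- function(responses) {
  eg <- responses[responses$group == "EG", ]
  eg <- dplyr::arrange(eg, dplyr::desc(.data$pct_change))
  eg$rank <- factor(seq_len(nrow(eg)))
  ggplot2::ggplot(eg, ggplot2::aes(x = .data$rank, y = .data$pct_change)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = mean(eg$pct_change),
                        linetype = "dashed") +
    ggplot2::labs(x = "Participant (ranked)",
                  y = "Cooper run improvement (%)") +
    ggplot2::theme_minimal()
}

#' Screen p-value plot
#'
#' Minus-log10 chi-square p-values across the screened panel with the
#' primary and secondary band thresholds; retained SNPs are highlighted.
#'
#' @param run A `tgs_run` from [run_discovery()].
#' @param alpha,secondary_max Band thresholds to draw (defaults 0.05 and
#'   0.075).
#' @return A ggplot.
#' @export
plot_screen <- function(run, alpha = 0.05, secondary_max = 0.075) {
  stopifnot(inherits(run, "tgs_run"))
  tab <- run$screen
  tab$index <- seq_len(nrow(tab))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$index,
                                    y = -log10(.data$chi2_p),
                                    colour = .data$retained)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(secondary_max),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "SNP (ordered by screen p-value)",
                  y = expression(-log[10](p)), colour = "retained") +
    ggplot2::theme_minimal()
}
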