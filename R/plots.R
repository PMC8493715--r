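#' Plot TRGV usage proportions
#'
#' Bar chart of mean per-gene usage with bootstrap 95% intervals, faceted by
#' tissue, mirroring the standard repertoire usage display.
#'
#' @param object A `trgv_usage` object ([usage_proportions()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trgv_usage <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$v_group, y = .data$mean_prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$tissue),
                        cols = ggplot2::vars(.data$line)) +
    ggplot2::labs(x = "TRGV gene", y = "proportion of repertoire") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot publicity bin shares per V gene
#'
#' Stacked bars of the read-weighted share of each publicity bin within each
#' V gene.
#'
#' @param shares Output of [public_fraction_by_v()].
#' @return A ggplot object.
#' @export
plot_publicity <- function(shares) {
  shares |>
    ggplot2::ggplot(ggplot2::aes(x = .data$v_group, y = .data$share,
                                 fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(private = "grey80", p60 = "#fdcc8a",
                                          p80 = "#fc8d59", p100 = "#d7301f")) +
    ggplot2::labs(x = "TRGV gene", y = "share of reads",
                  fill = "publicity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot coverage-standardised diversity estimates
#'
#' @param diversity Output of [repertoire_diversity()].
#' @param x Column mapped to the x axis (default `"tissue"`).
#' @return A ggplot object.
#' @export
plot_diversity <- function(diversity, x = "tissue") {
  p <- diversity |>
    ggplot2::ggplot(ggplot2::aes(x = .data[[x]], y = .data$estimate)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1,
                                                            seed = 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$q), scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(y = "effective number of clonotypes") +
    ggplot2::theme_minimal()
  p
}

#' Plot RSS score against usage with the fitted regression line
#'
#' @param object An `rss_usage_fit` ([usage_regression()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rss_usage_fit <- function(object, ...) {
  object$data |>
    ggplot2::ggplot(ggplot2::aes(x = .data$score, y = .data$usage)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "RSS score (log-odds)",
                  y = "proportion of thymic repertoire",
                  subtitle = sprintf("R² = %.4f, p = %.3g",
                                     object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}
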