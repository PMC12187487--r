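#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means, with horizontal
#' lines at the mean difference and at the limits of agreement
#' (mean +/- 1.96 SD).
#'
#' @param object A [bland_altman()] object.
#' @param ... Ignored.
#' @return A ggplot.
#' @examples
#' set.seed(1)
#' autoplot(bland_altman(rnorm(50, 100, 10), rnorm(50, 100, 10)))
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$pair_diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = s$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(s$loa_low, s$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two measures",
                  y = "Difference between measures",
                  title = sprintf(
                    "Bland-Altman: mean diff %.3g, LoA [%.3g, %.3g]",
                    s$mean_diff, s$loa_low, s$loa_high)) +
    ggplot2::theme_minimal()
}

#' @export
plot.bland_altman <- function(x, ...) print(autoplot(x, ...))

#' Dot plot of validity correlations by pair and window
#'
#' @param object A `validity_report`.
#' @param ... Ignored.
#' @return A ggplot showing Spearman's rho per variable pair, coloured by
#'   interpretation band, faceted by exposure window.
#' @export
autoplot.validity_report <- function(object, ...) {
  d <- object$table %>% filter(.data$estimable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho, y = .data$pair,
                                  colour = .data$band)) +
    ggplot2::geom_vline(xintercept = c(0.20, 0.50), linetype = "dotted") +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~window) +
    ggplot2::xlim(min(0, min(d$rho)), 1) +
    ggplot2::labs(x = "Spearman's rho", y = NULL, colour = "band",
                  title = "Intake vs biomarker correlations") +
    ggplot2::theme_minimal()
}

#' @export
plot.validity_report <- function(x, ...) print(autoplot(x, ...))

#' Dot plot of round-1 vs round-2 reproducibility correlations
#'
#' @param object A `reproducibility_report`.
#' @param ... Ignored.
#' @return A ggplot of Spearman's rho per variable, coloured by band.
#' @export
autoplot.reproducibility_report <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho,
                                  y = stats::reorder(.data$variable,
                                                     .data$rho),
                                  colour = .data$band)) +
    ggplot2::geom_vline(xintercept = c(0.20, 0.50), linetype = "dotted") +
    ggplot2::geom_point(size = 3) +
    ggplot2::xlim(min(0, min(d$rho)), 1) +
    ggplot2::labs(x = "Spearman's rho (round 1 vs round 2)", y = NULL,
                  title = "Reproducibility of the weighed food record") +
    ggplot2::theme_minimal()
}

#' @export
plot.reproducibility_report <- function(x, ...) print(autoplot(x, ...))
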