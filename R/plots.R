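#' Bland-Altman plot
#'
#' Differences (alternate - criterion) against per-athlete means, with the
#' mean difference (solid), the 95% limits of agreement (dashed) and the
#' proportional-bias regression line.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "Mean of methods (kg)",
                  y = "Difference, alternate - criterion (kg)") +
    ggplot2::theme_minimal()
}

#' Method-agreement overview plot
#'
#' Mean difference with 95% limits of agreement for every method and stratum
#' of a validation run; equivalence margin shown as dotted lines.
#'
#' @param run A `validation_run`.
#' @return A ggplot.
#' @export
plot_method_agreement <- function(run) {
  stopifnot(inherits(run, "validation_run"))
  agr <- dplyr::left_join(run$agreement,
                          method_catalog()[, c("method_id", "label")],
                          by = "method_id")
  agr$label <- factor(agr$label, levels = rev(method_catalog()$label))
  m <- run$config$margin_kg
  ggplot2::ggplot(agr, ggplot2::aes(x = .data$mean_diff, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(-m, m), linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$loa_low,
                                         xmax = .data$loa_high),
                            height = 0.3, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tost_equivalent),
                        size = 2) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Mean difference vs criterion (kg), with 95% LoA",
                  y = NULL, colour = "TOST equivalent") +
    ggplot2::theme_minimal()
}

#' @rdname plot_method_agreement
#' @param object A `validation_run`.
#' @param ... Unused.
#' @method autoplot validation_run
#' @export
autoplot.validation_run <- function(object, ...) plot_method_agreement(object)
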