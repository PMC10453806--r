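#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 slope = x$slope, slope_p = x$slope_p,
                 intercept = x$intercept)
}

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, proportional_bias = x$proportional_bias,
                 alpha = x$alpha)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (alternate - criterion), n = %d\n  MD %.3f, LoA [%.3f, %.3f]\n  slope %.4f (p = %s)%s\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high, x$slope,
    ifelse(is.na(x$slope_p), "NA", sprintf("%.4g", x$slope_p)),
    if (x$proportional_bias) " -> proportional bias" else ""))
  invisible(x)
}

#' @method tidy tost
#' @export
tidy.tost <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 margin = x$margin, equivalent = x$equivalent)
}

#' @export
print.tost <- function(x, ...) {
  cat(sprintf(
    "Paired TOST: MD %.3f, %.0f%% CI [%.3f, %.3f], margin +/-%.3g kg -> %s\n",
    x$mean_diff, 100 * (1 - 2 * x$alpha), x$ci_low, x$ci_high, x$margin,
    if (x$equivalent) "equivalent" else "NOT equivalent"))
  invisible(x)
}

#' @method tidy validation_run
#' @export
tidy.validation_run <- function(x, ...) x$agreement

#' @method glance validation_run
#' @export
glance.validation_run <- function(x, ...) {
  tibble::tibble(
    n_athletes = length(unique(x$estimates$id)),
    n_methods = length(unique(x$estimates$method_id)),
    n_strata = length(unique(x$estimates$stratum)),
    criterion = x$config$criterion,
    field3c_skf = x$config$field3c_skf,
    margin_kg = x$config$margin_kg,
    alpha = x$config$alpha)
}

#' @export
print.validation_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "validation_run: %d athletes, %d methods, %d stratum/strata (criterion %s)\n",
    g$n_athletes, g$n_methods, g$n_strata, g$criterion))
  cat("agreement table (tidy(x)):\n")
  print(x$agreement)
  invisible(x)
}
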