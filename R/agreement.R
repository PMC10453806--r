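# Difference orientation throughout this module: alternate - criterion.
# A positive mean difference means the alternate method OVERestimates.
paired_complete <- function(data, criterion, alternate, min_n) {
  stopifnot(is.data.frame(data), criterion %in% names(data),
            alternate %in% names(data))
  keep <- stats::complete.cases(data[[criterion]], data[[alternate]])
  out <- data[keep, , drop = FALSE]
  if (nrow(out) < min_n) {
    stop("insufficient data: ", nrow(out), " complete pair(s), need >= ",
         min_n, call. = FALSE)
  }
  out
}

#' Mean and SD of paired method differences
#'
#' Differences are oriented alternate - criterion: a positive mean difference
#' means the alternate method overestimates relative to the criterion. The SD
#' uses the n - 1 denominator. Incomplete pairs are dropped.
#'
#' @param data Data frame of paired per-athlete values.
#' @param criterion,alternate Names of the criterion and alternate columns.
#' @return One-row tibble: `n`, `mean_diff`, `sd_diff`.
#' @export
difference_summary <- function(data, criterion = "criterion",
                               alternate = "alternate") {
  data <- paired_complete(data, criterion, alternate, min_n = 2L)
  d <- data[[alternate]] - data[[criterion]]
  tibble::tibble(n = length(d), mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Bland-Altman agreement analysis with proportional-bias regression
#'
#' Computes the 95% limits of agreement, mean difference +/- 1.96 SD of the
#' differences (alternate - criterion), and regresses the difference on the
#' per-athlete mean of the two methods by ordinary least squares. A slope
#' whose two-sided t-test p-value falls below `alpha` indicates proportional
#' bias (the disagreement grows or shrinks with the size of the measurement).
#'
#' @inheritParams difference_summary
#' @param alpha Significance level for the proportional-bias test
#'   (default 0.05).
#' @return An object of class `bland_altman`; use [generics::tidy()] for a
#'   one-row summary, [generics::glance()] for the verdict, and
#'   [ggplot2::autoplot()] for the standard plot. Fields include `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `slope`, `slope_p`, `intercept`,
#'   `proportional_bias` and the per-athlete `points`.
#' @export
bland_altman <- function(data, criterion = "criterion",
                         alternate = "alternate", alpha = 0.05) {
  data <- paired_complete(data, criterion, alternate, min_n = 3L)
  x <- data[[criterion]]
  y <- data[[alternate]]
  d <- y - x
  m <- (x + y) / 2
  if (stats::sd(m) == 0) {
    stop("degenerate input: zero variance of per-athlete means; ",
         "proportional-bias slope undefined", call. = FALSE)
  }
  md <- mean(d)
  sdd <- stats::sd(d)
  fit <- stats::lm(d ~ m)
  # constant differences give an exactly perfect fit; lm's reliability
  # warning is expected and the slope p is set to NA below
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(cf["m", "Estimate"])
  # constant differences leave zero residual variance; the slope is exactly 0
  # and no proportional bias can be claimed
  slope_p <- if (nrow(cf) == 2 && is.finite(cf["m", "Pr(>|t|)"])) {
    unname(cf["m", "Pr(>|t|)"])
  } else {
    NA_real_
  }
  structure(list(
    n = length(d),
    mean_diff = md, sd_diff = sdd,
    loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
    slope = slope, slope_p = slope_p,
    intercept = unname(cf["(Intercept)", "Estimate"]),
    alpha = alpha,
    proportional_bias = isTRUE(!is.na(slope_p) && slope_p < alpha),
    points = tibble::tibble(mean = m, diff = d)
  ), class = "bland_altman")
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with variances and
#' covariance computed with 1/n (population) denominators — Lin's original
#' convention. The CCC penalises both dispersion and location shift, so
#' |CCC| <= |r| always.
#'
#' @param x,y Numeric vectors of paired measurements.
#' @return The concordance correlation coefficient.
#' @examples
#' lin_ccc(1:3, 2:4) # 4/7
#' @export
lin_ccc <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("insufficient data: need >= 2 pairs", call. = FALSE)
  vx <- mean((x - mean(x))^2)
  vy <- mean((y - mean(y))^2)
  if (vx == 0 || vy == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * sxy / (vx + vy + (mean(x) - mean(y))^2)
}

#' Standard error of the estimate
#'
#' Residual standard error (n - 2 denominator) from the ordinary
#' least-squares regression of the criterion on the alternate method — the
#' typical error left after the best linear recalibration of the alternate.
#'
#' @param criterion,alternate Numeric vectors of paired measurements.
#' @return SEE in the units of the inputs (kg here).
#' @export
see <- function(criterion, alternate) {
  keep <- stats::complete.cases(criterion, alternate)
  criterion <- criterion[keep]; alternate <- alternate[keep]
  if (length(criterion) < 3) {
    stop("insufficient data: need >= 3 pairs", call. = FALSE)
  }
  fit <- stats::lm(criterion ~ alternate)
  sqrt(sum(stats::residuals(fit)^2) / (length(criterion) - 2))
}

#' Paired TOST equivalence test
#'
#' Two one-sided tests at `alpha` per side: the methods are declared
#' equivalent when the 90% confidence interval of the mean difference
#' (alternate - criterion), mean_diff +/- t(1 - alpha, n - 1) sd_diff/sqrt(n),
#' falls entirely inside \[-margin, +margin\] (default margin 2 kg).
#' With zero difference variance the CI degenerates to the mean difference
#' itself and equivalence reduces to |mean_diff| < margin.
#'
#' @inheritParams difference_summary
#' @param margin Equivalence margin in kg, > 0 (default 2).
#' @param alpha One-sided test level (default 0.05, i.e. a 90% CI).
#' @return An object of class `tost` with fields `equivalent`, `ci_low`,
#'   `ci_high`, `mean_diff`, `sd_diff`, `n`, `margin`, `alpha`;
#'   [generics::tidy()] returns them as a one-row tibble.
#' @export
tost_paired <- function(data, criterion = "criterion",
                        alternate = "alternate", margin = 2, alpha = 0.05) {
  stopifnot(margin >= 0)
  data <- paired_complete(data, criterion, alternate, min_n = 3L)
  d <- data[[alternate]] - data[[criterion]]
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    ci <- c(md, md)
    eq <- abs(md) < margin
  } else {
    half <- stats::qt(1 - alpha, df = n - 1) * sdd / sqrt(n)
    ci <- c(md - half, md + half)
    eq <- ci[1] >= -margin && ci[2] <= margin
  }
  structure(list(equivalent = eq, ci_low = ci[1], ci_high = ci[2],
                 mean_diff = md, sd_diff = sdd, n = n,
                 margin = margin, alpha = alpha),
            class = "tost")
}

#' Repeated-measures ANOVA with Holm-adjusted follow-ups
#'
#' One-way within-subject ANOVA across methods (each athlete measured by every
#' method; athletes missing any method are dropped listwise), followed by
#' paired t-tests of each method against the reference with Holm step-down
#' adjustment across the family. No sphericity correction is applied by
#' default (`sphericity_correction = "none"` is the only implemented option;
#' the argument is a config hook).
#'
#' @param data Long tibble with one row per athlete x method.
#' @param value,method,id Names of the value, method and athlete-id columns.
#' @param reference Method label used as the comparison reference.
#' @param sphericity_correction Currently only `"none"`.
#' @return List with `anova` (one-row tibble: `f`, `df1`, `df2`, `p`,
#'   `n_complete`) and `contrasts` (tibble per non-reference method:
#'   `method`, `mean_diff`, `t`, `df`, `p_raw`, `p_holm`).
#' @export
rm_anova_holm <- function(data, value = "value", method = "method",
                          id = "id", reference,
                          sphericity_correction = "none") {
  sphericity_correction <- match.arg(sphericity_correction)
  df <- tibble::tibble(
    id = as.character(data[[id]]),
    method = as.character(data[[method]]),
    value = data[[value]])
  methods <- unique(df$method)
  if (!reference %in% methods) {
    stop("reference method '", reference, "' not present", call. = FALSE)
  }
  if (length(methods) < 2) stop("need >= 2 methods", call. = FALSE)
  wide <- tidyr::pivot_wider(df, names_from = "method", values_from = "value")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3) {
    stop("insufficient data: fewer than 3 complete athletes", call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"id", names_to = "method",
                              values_to = "value")
  long$id <- factor(long$id)
  long$method <- factor(long$method)

  if (stats::sd(long$value) == 0) {
    an <- tibble::tibble(f = 0, df1 = length(methods) - 1L,
                         df2 = (nrow(wide) - 1L) * (length(methods) - 1L),
                         p = 1, n_complete = nrow(wide))
  } else {
    fit <- stats::aov(value ~ method + Error(id), data = long)
    within <- summary(fit)[["Error: Within"]][[1]]
    an <- tibble::tibble(
      f = within["method", "F value"],
      df1 = within["method", "Df"],
      df2 = within["Residuals", "Df"],
      p = within["method", "Pr(>F)"],
      n_complete = nrow(wide))
  }

  others <- setdiff(methods, reference)
  contrasts <- purrr::map_dfr(others, function(m) {
    d <- wide[[m]] - wide[[reference]]
    n <- length(d)
    md <- mean(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      tstat <- if (md == 0) 0 else sign(md) * Inf
      p <- if (md == 0) 1 else 0
    } else {
      tstat <- md / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
    tibble::tibble(method = m, mean_diff = md, t = tstat,
                   df = n - 1L, p_raw = p)
  })
  contrasts$p_holm <- stats::p.adjust(contrasts$p_raw, method = "holm")
  list(anova = an, contrasts = contrasts)
}

#' Test-retest intraclass correlation for replicate readings
#'
#' Two-way mixed-effects, consistency, single-measure ICC — ICC(3,1) — for
#' replicate measurements of fixed targets (e.g. the three caliper readings at
#' each athlete x site). With target mean squares MSB and residual MSE from
#' the two-way ANOVA (targets x replicate position),
#' ICC = (MSB - MSE) / (MSB + (k - 1) MSE), with the F-based 95% confidence
#' interval of Shrout & Fleiss.
#'
#' @param ratings Matrix or data frame, one row per target, one column per
#'   replicate position; >= 5 targets, >= 2 replicates.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n_targets`,
#'   `k_replicates`.
#' @export
icc_test_retest <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5 || k < 2) {
    stop("insufficient data: need >= 5 targets with >= 2 replicates",
         call. = FALSE)
  }
  if (stats::sd(as.vector(m)) == 0) {
    stop("degenerate input: all readings identical", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msb <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msb - mse) / (msb + (k - 1) * mse)
  alpha <- 1 - conf_level
  f0 <- msb / mse
  fl <- f0 / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- f0 * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  tibble::tibble(
    icc = icc,
    ci_low = (fl - 1) / (fl + k - 1),
    ci_high = (fu - 1) / (fu + k - 1),
    n_targets = n, k_replicates = k)
}

#' Skinfold technician reliability from a cohort's replicate readings
#'
#' Stacks every athlete x site triplicate into the target-by-replicate matrix
#' and computes the test-retest ICC of [icc_test_retest()].
#'
#' @param cohort Cohort tibble carrying `sf_<site>_<rep>_mm` columns.
#' @inheritParams icc_test_retest
#' @return As [icc_test_retest()].
#' @export
skinfold_icc <- function(cohort, conf_level = 0.95) {
  blocks <- lapply(skinfold_sites(), function(site) {
    cols <- sprintf("sf_%s_%d_mm", site, 1:3)
    if (!all(cols %in% names(cohort))) return(NULL)
    as.matrix(cohort[cols])
  })
  m <- do.call(rbind, blocks)
  if (is.null(m)) stop("no replicate columns found", call. = FALSE)
  icc_test_retest(m, conf_level = conf_level)
}

#' Full per-method agreement report against the criterion
#'
#' One call computing every validity metric for one alternate method:
#' alternate mean/SD, mean difference and its SD (alternate - criterion),
#' Bland-Altman 95% limits of agreement and proportional-bias slope/p,
#' Pearson's r, Lin's CCC, SEE, and the paired TOST verdict at the given
#' margin.
#'
#' @inheritParams bland_altman
#' @param method_id Label carried into the report row.
#' @param margin TOST equivalence margin in kg.
#' @return One-row tibble with the `AgreementReport` fields (`holm_p` is
#'   `NA` here; the pipeline fills it from the RM-ANOVA family).
#' @export
agreement_report <- function(data, method_id = "alternate",
                             criterion = "criterion", alternate = "alternate",
                             margin = 2, alpha = 0.05) {
  data <- paired_complete(data, criterion, alternate, min_n = 3L)
  x <- data[[criterion]]
  y <- data[[alternate]]
  ba <- bland_altman(data, criterion, alternate, alpha = alpha)
  tost <- tost_paired(data, criterion, alternate, margin = margin,
                      alpha = alpha)
  tibble::tibble(
    method_id = method_id,
    n = length(y),
    mean_alt = mean(y), sd_alt = stats::sd(y),
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    ba_slope = ba$slope, ba_slope_p = ba$slope_p,
    pearson_r = stats::cor(x, y),
    ccc = lin_ccc(x, y),
    see = see(x, y),
    tost_equivalent = tost$equivalent,
    tost_ci_low = tost$ci_low, tost_ci_high = tost$ci_high,
    holm_p = NA_real_)
}
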