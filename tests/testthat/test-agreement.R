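paired_tbl <- function(crit, alt) tibble::tibble(criterion = crit, alternate = alt)

test_that("difference summary orientation and worked values", {
  expect_equal(
    difference_summary(paired_tbl(c(50, 60, 70), c(51, 61, 71))),
    tibble::tibble(n = 3L, mean_diff = 1, sd_diff = 0))
  d <- difference_summary(paired_tbl(c(50, 60), c(51, 63)))
  expect_equal(d$mean_diff, 2)
  expect_equal(d$sd_diff, sqrt(2), tolerance = 1e-9)
  same <- difference_summary(paired_tbl(1:5, 1:5))
  expect_equal(same$mean_diff, 0)
  expect_error(difference_summary(paired_tbl(1, 2)), "insufficient")
})

test_that("Bland-Altman: constant shift, exact noiseless slope recovery, identity", {
  ba <- bland_altman(paired_tbl(c(50, 60, 70), c(51, 61, 71)))
  expect_equal(c(ba$loa_low, ba$loa_high), c(1, 1))
  expect_equal(ba$slope, 0, tolerance = 1e-12)
  expect_false(ba$proportional_bias)

  # differences constructed as d = -0.2 * mean + c, recovered exactly
  m <- seq(40, 80, length.out = 15)
  d <- -0.2 * m + 3
  crit <- m - d / 2
  alt <- m + d / 2
  ba2 <- bland_altman(paired_tbl(crit, alt))
  expect_equal(ba2$slope, -0.2, tolerance = 1e-10)

  ident <- bland_altman(paired_tbl(c(50, 60, 70), c(50, 60, 70)))
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
  expect_false(ident$proportional_bias)

  expect_error(bland_altman(paired_tbl(c(50, 50, 50), c(50, 50, 50))),
               "degenerate")
})

test_that("Lin's CCC uses population moments and respects its inequality", {
  expect_equal(lin_ccc(1:3, 1:3), 1)
  expect_equal(lin_ccc(1:3, 2:4), 4 / 7, tolerance = 1e-12)
  expect_equal(lin_ccc(1:3, -(1:3)), -1 / 13, tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1, 1), 1:3), "degenerate")
  set.seed(11)
  for (i in 1:50) {
    p <- random_paired(sample(5:40, 1), shift = stats::rnorm(1),
                       slope = stats::runif(1, 0.5, 1.5))
    expect_lte(abs(lin_ccc(p$criterion, p$alternate)) + 1e-12,
               abs(stats::cor(p$criterion, p$alternate)) + 1e-9)
  }
  # CCC = r exactly when means and variances match
  x <- c(1, 2, 4, 7)
  y <- rev(x)
  expect_equal(lin_ccc(x, y), stats::cor(x, y), tolerance = 1e-12)
})

test_that("SEE: zero for exact linearity, frozen worked value, algebraic identity", {
  x <- seq(40, 70, length.out = 10)
  expect_equal(see(0.9 * x + 3, x), 0, tolerance = 1e-10)
  expect_equal(see(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.9486832981,
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    p <- random_paired(sample(5:30, 1))
    n <- nrow(p)
    r <- stats::cor(p$criterion, p$alternate)
    ident <- stats::sd(p$criterion) * sqrt(1 - r^2) * sqrt((n - 1) / (n - 2))
    expect_equal(see(p$criterion, p$alternate), ident, tolerance = 1e-10)
  }
  expect_error(see(1:2, 2:3), "insufficient")
})

test_that("paired TOST: degenerate zero CI, t-quantile CI, zero margin", {
  z <- tost_paired(paired_tbl(rep(50, 10), rep(50, 10)))
  expect_true(z$equivalent)

  # fixed vector with exact mean 3.0 and sd 0.5, n = 20
  base <- scale(stats::rnorm(20))[, 1]
  d <- 3 + 0.5 * base
  crit <- stats::runif(20, 40, 80)
  tost <- tost_paired(paired_tbl(crit, crit + d))
  half <- stats::qt(0.95, 19) * 0.5 / sqrt(20)
  expect_equal(c(tost$ci_low, tost$ci_high), c(3 - half, 3 + half),
               tolerance = 1e-9)
  expect_false(tost$equivalent)
  expect_equal(round(c(tost$ci_low, tost$ci_high), 2), c(2.81, 3.19))

  tiny <- tost_paired(paired_tbl(crit, crit + 0.01 * base), margin = 1e-9)
  expect_false(tiny$equivalent)

  # monotone in margin: equivalent at m implies equivalent at any larger m
  p <- random_paired(25, shift = 0.8, slope = 1, noise = 1.5)
  margins <- c(0.5, 1, 2, 4, 8)
  verdicts <- vapply(margins,
                     function(m) tost_paired(p, margin = m)$equivalent,
                     logical(1))
  expect_true(all(diff(as.integer(verdicts)) >= 0))
})

test_that("RM-ANOVA with Holm: null case, frozen Holm arithmetic, huge shift", {
  ids <- sprintf("a%02d", 1:12)
  long <- tidyr::expand_grid(id = ids, method = c("crit", "m1", "m2"))
  long$value <- 60
  null <- rm_anova_holm(long, reference = "crit")
  expect_equal(null$anova$f, 0)
  expect_true(all(null$contrasts$p_holm == 1))

  expect_equal(o_holm(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))

  set.seed(21)
  base <- stats::rnorm(20, 60, 8)
  ids2 <- sprintf("b%02d", 1:20)
  long2 <- dplyr::bind_rows(
    tibble::tibble(id = ids2, method = "crit", value = base),
    tibble::tibble(id = ids2, method = "shifted",
                   value = base + 5 + stats::rnorm(20, 0, 0.1)),
    tibble::tibble(id = ids2, method = "close",
                   value = base + stats::rnorm(20, 0, 0.5)))
  res <- rm_anova_holm(long2, reference = "crit")
  expect_lt(res$contrasts$p_holm[res$contrasts$method == "shifted"], 1e-6)
  expect_lt(res$anova$p, 1e-6)
  expect_true(all(res$contrasts$p_holm >= res$contrasts$p_raw))
  # Holm preserves the identity of the smallest-p method
  expect_equal(res$contrasts$method[which.min(res$contrasts$p_holm)],
               res$contrasts$method[which.min(res$contrasts$p_raw)])
})

test_that("athletes missing any method are dropped listwise from the ANOVA", {
  long <- tidyr::expand_grid(id = sprintf("a%d", 1:10),
                             method = c("crit", "m1"))
  set.seed(5)
  long$value <- stats::rnorm(nrow(long), 60, 5)
  long <- long[!(long$id == "a1" & long$method == "m1"), ]
  res <- rm_anova_holm(long, reference = "crit")
  expect_equal(res$anova$n_complete, 9)
  expect_error(rm_anova_holm(long[long$id %in% c("a2", "a3"), ],
                             reference = "crit"), "insufficient")
})

test_that("test-retest ICC: perfect, noise-dominated, and variance-ratio cases", {
  targets <- seq(5, 40, length.out = 30)
  perfect <- cbind(targets, targets, targets)
  expect_equal(icc_test_retest(perfect)$icc, 1, tolerance = 1e-12)

  set.seed(9)
  # replicate noise sd equal to between-target sd -> ICC ~ 0.5
  bt <- stats::rnorm(4000, 20, 4)
  eq <- sapply(1:3, function(i) bt + stats::rnorm(4000, 0, 4))
  expect_equal(icc_test_retest(eq)$icc, 0.5, tolerance = 0.05)

  # no between-target variance -> ICC ~ 0
  flat <- sapply(1:3, function(i) 20 + stats::rnorm(2000, 0, 2))
  expect_lt(abs(icc_test_retest(flat)$icc), 0.05)

  icc <- icc_test_retest(eq)
  expect_lt(icc$ci_low, icc$icc)
  expect_gt(icc$ci_high, icc$icc)
  expect_error(icc_test_retest(matrix(5, 10, 3)), "degenerate")
  expect_error(icc_test_retest(matrix(1:6, 3, 2)), "insufficient")
})

test_that("agreement statistics match the brute-force oracle on random datasets", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    p <- random_paired(n, shift = stats::rnorm(1, 0, 2),
                       slope = stats::runif(1, 0.7, 1.3),
                       noise = stats::runif(1, 0.2, 3))
    x <- p$criterion; y <- p$alternate

    ds <- difference_summary(p)
    expect_equal(c(ds$mean_diff, ds$sd_diff),
                 unname(o_md_sd(x, y)), tolerance = 1e-10)

    ba <- bland_altman(p)
    expect_equal(c(ba$loa_low, ba$loa_high), unname(o_loa(x, y)),
                 tolerance = 1e-10)
    oslope <- o_ba_slope(x, y)
    expect_equal(ba$slope, oslope[["slope"]], tolerance = 1e-10)
    expect_equal(ba$slope_p, oslope[["p"]], tolerance = 1e-10)

    expect_equal(stats::cor(x, y), o_r(x, y), tolerance = 1e-10)
    expect_equal(lin_ccc(x, y), o_ccc(x, y), tolerance = 1e-10)
    expect_equal(see(x, y), o_see(x, y), tolerance = 1e-10)

    tost <- tost_paired(p, margin = 2)
    ot <- o_tost(x, y, margin = 2)
    expect_equal(c(tost$ci_low, tost$ci_high), ot$ci, tolerance = 1e-10)
    expect_identical(tost$equivalent, ot$equivalent)
  }
})

test_that("Holm-adjusted contrasts match the step-down oracle on random families", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    k <- sample(3:6, 1)
    ids <- sprintf("a%02d", 1:n)
    base <- stats::rnorm(n, 60, 7)
    long <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
      v <- if (j == 1) base else base + stats::rnorm(1, 0, 1) +
        stats::rnorm(n, 0, 2)
      tibble::tibble(id = ids, method = paste0("m", j), value = v)
    }))
    res <- rm_anova_holm(long, reference = "m1")
    raw <- vapply(res$contrasts$method, function(m) {
      o_paired_t_p(base, long$value[long$method == m])
    }, numeric(1))
    expect_equal(res$contrasts$p_raw, unname(raw), tolerance = 1e-10)
    expect_equal(res$contrasts$p_holm, unname(o_holm(raw)), tolerance = 1e-10)
  }
})

test_that("limits of agreement contain about 95% of large normal samples", {
  set.seed(31)
  n <- 20000
  crit <- stats::rnorm(n, 55, 8)
  alt <- crit + stats::rnorm(n, 0.5, 2)
  ba <- bland_altman(tibble::tibble(criterion = crit, alternate = alt))
  d <- alt - crit
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("agreement report assembles all metrics coherently", {
  set.seed(15)
  p <- random_paired(40, shift = 1, slope = 1.05, noise = 1.5)
  rep_ <- agreement_report(p, method_id = "m")
  expect_equal(rep_$n, 40)
  expect_lte(abs(rep_$ccc), abs(rep_$pearson_r))
  expect_lte(rep_$loa_low, rep_$mean_diff)
  expect_gte(rep_$loa_high, rep_$mean_diff)
  expect_gte(rep_$see, 0)
  expect_equal(rep_$mean_alt, mean(p$alternate))
  tidy_ba <- tidy(bland_altman(p))
  expect_equal(rep_$ba_slope, tidy_ba$slope)
})
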