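# Brute-force reference implementations used as independent oracles.
# Direct formula evaluation only; deliberately shares no code with the
# package internals (explicit sums, no sd()/cor()/lm()).
o_mean <- function(x) sum(x) / length(x)
o_sd <- function(x) sqrt(sum((x - o_mean(x))^2) / (length(x) - 1))

o_md_sd <- function(crit, alt) {
  d <- alt - crit
  c(md = o_mean(d), sd = o_sd(d))
}

o_loa <- function(crit, alt) {
  s <- o_md_sd(crit, alt)
  c(low = s[["md"]] - 1.96 * s[["sd"]], high = s[["md"]] + 1.96 * s[["sd"]])
}

o_ols <- function(x, y) {
  b <- sum((x - o_mean(x)) * (y - o_mean(y))) / sum((x - o_mean(x))^2)
  list(b = b, a = o_mean(y) - b * o_mean(x))
}

o_ba_slope <- function(crit, alt) {
  d <- alt - crit
  m <- (alt + crit) / 2
  f <- o_ols(m, d)
  n <- length(d)
  res <- d - (f$a + f$b * m)
  se_b <- sqrt((sum(res^2) / (n - 2)) / sum((m - o_mean(m))^2))
  tstat <- f$b / se_b
  c(slope = f$b, p = 2 * stats::pt(-abs(tstat), n - 2))
}

o_r <- function(x, y) {
  sum((x - o_mean(x)) * (y - o_mean(y))) /
    sqrt(sum((x - o_mean(x))^2) * sum((y - o_mean(y))^2))
}

o_ccc <- function(x, y) {
  n <- length(x)
  vx <- sum((x - o_mean(x))^2) / n
  vy <- sum((y - o_mean(y))^2) / n
  sxy <- sum((x - o_mean(x)) * (y - o_mean(y))) / n
  2 * sxy / (vx + vy + (o_mean(x) - o_mean(y))^2)
}

o_see <- function(crit, alt) {
  f <- o_ols(alt, crit)
  res <- crit - (f$a + f$b * alt)
  sqrt(sum(res^2) / (length(crit) - 2))
}

o_tost <- function(crit, alt, margin, alpha = 0.05) {
  d <- alt - crit
  n <- length(d)
  half <- stats::qt(1 - alpha, n - 1) * o_sd(d) / sqrt(n)
  ci <- c(o_mean(d) - half, o_mean(d) + half)
  list(ci = ci, equivalent = ci[1] >= -margin && ci[2] <= margin)
}

# Holm step-down by explicit loop
o_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[ord[k]])
    adj[ord[k]] <- min(1, running)
  }
  adj
}

o_paired_t_p <- function(crit, alt) {
  d <- alt - crit
  n <- length(d)
  tstat <- o_mean(d) / (o_sd(d) / sqrt(n))
  2 * stats::pt(-abs(tstat), n - 1)
}
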