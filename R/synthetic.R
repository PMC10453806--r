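#' Configuration for the synthetic athlete cohort generator
#'
#' Defaults emulate the measurement structure of a mixed-sex youth-athlete
#' study: 51 female and 40 male athletes aged 14-25 (18.19 +/- 2.37 y), height
#' 172.1 +/- 9.8 cm, body mass 68.9 +/- 14.5 kg, pooled body fat
#' 19.59 +/- 6.9%, fat-free-mass hydration 0.732. The pooled body-fat
#' distribution is split by sex: female mean = `bf_mean + bf_sex_offset / 2`,
#' male mean = `bf_mean - bf_sex_offset / 2`, with the per-sex SD shrunk to
#' `sqrt(bf_sd^2 - (bf_sex_offset / 2)^2)` so that the pooled moments match
#' the configured values for balanced sexes.
#'
#' Noise scales are measurement-level: densitometry noise on the density
#' scale (`db_noise_sd`, kg/L), spectroscopy water noise in litres, caliper
#' site noise and technician replicate noise in mm, resistance noise in ohms.
#' `device_bias` perturbs consumer-device body-fat outputs: a named list,
#' each element `c(additive = <BF points>, proportional = <slope>)` applied
#' as `bf + additive + proportional * (bf_true - bf_mean)`.
#'
#' @param n_female,n_male Athletes per sex.
#' @param seed Integer seed; same seed and config give a bit-identical cohort.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated.
#' @param height_mean,height_sd,height_range Height (cm), truncated.
#' @param bm_mean,bm_sd,bm_range Body mass (kg), truncated.
#' @param bf_mean,bf_sd,bf_sex_offset,bf_range True body-fat percent.
#' @param hydration_ffm TBW as a fraction of fat-free mass (default 0.732).
#' @param hydration_noise_sd Biological hydration noise (L).
#' @param db_noise_sd,adp_db_noise_sd Densitometry noise (kg/L).
#' @param bis_tbw_noise_sd Spectroscopy TBW measurement noise (L).
#' @param r_noise_sd,xc_mean,xc_sd Impedance: resistance noise (ohm) and the
#'   reactance distribution.
#' @param site_noise_sd Per-site skinfold noise (mm) around the value implied
#'   by the generating equation.
#' @param replicate_noise_sd Technician noise (mm) across the 3 replicate
#'   readings of a site.
#' @param site_weights Relative thickness of the 8 sites; shapes how the
#'   generating equation's aggregate is distributed, config-overridable.
#' @param generating_equation Equation whose estimate the skinfolds are
#'   constructed to reproduce (default `"evans7"`); any skinfold equation id
#'   from [equation_registry()].
#' @param devices Consumer devices emitting opaque BF% columns
#'   (`bf_<device>_pct`).
#' @param device_bias Named list of per-device `c(additive, proportional)`
#'   biases (BF-percent scale).
#' @param device_bf_noise_sd Device BF% noise (percent points).
#' @param max_retries Resampling bound per athlete before erroring.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_female = 51, n_male = 40, seed = NULL,
                          age_mean = 18.19, age_sd = 2.37,
                          age_range = c(14, 25),
                          height_mean = 172.1, height_sd = 9.8,
                          height_range = c(145, 210),
                          bm_mean = 68.9, bm_sd = 14.5, bm_range = c(40, 130),
                          bf_mean = 19.59, bf_sd = 6.9, bf_sex_offset = 8,
                          bf_range = c(4, 45),
                          hydration_ffm = 0.732, hydration_noise_sd = 0.5,
                          db_noise_sd = 0.002, adp_db_noise_sd = 0.003,
                          bis_tbw_noise_sd = 0.3,
                          r_noise_sd = 5, xc_mean = 60, xc_sd = 8,
                          site_noise_sd = 1, replicate_noise_sd = 0.5,
                          site_weights = NULL,
                          generating_equation = "evans7",
                          devices = c("mfbia", "f2fbia"),
                          device_bias = list(),
                          device_bf_noise_sd = 2,
                          max_retries = 100L) {
  cfg <- as.list(environment())
  if (is.null(cfg$site_weights)) {
    cfg$site_weights <- c(subscapular = 10, triceps = 12, chest = 8,
                          midaxillary = 9, suprailiac = 13, abdominal = 16,
                          thigh = 18, biceps = 6)
  }
  stopifnot(
    cfg$n_female >= 0, cfg$n_male >= 0,
    cfg$hydration_ffm > 0, cfg$hydration_ffm < 1,
    all(vapply(cfg[grep("_sd$", names(cfg))], function(x) x >= 0, TRUE)),
    setequal(names(cfg$site_weights), skinfold_sites()),
    all(cfg$site_weights > 0))
  registry_lookup(cfg$generating_equation)  # must exist
  class(cfg) <- "cohort_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < range[1] | x > range[2]
  tries <- 0L
  while (any(bad) && tries < 1000L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < range[1] | x > range[2]
    tries <- tries + 1L
  }
  pmin(pmax(x, range[1]), range[2])
}

# member sites whose sum is the generating equation's aggregate input
generating_sites <- function(eq_id, sex) {
  if (eq_id == "jp3") return(jp3_sites(sex))
  row <- registry_lookup(eq_id)
  sites <- switch(eq_id,
                  evans3 = c("abdominal", "thigh", "triceps"),
                  row$required_sites[[1]])
  rep(list(sites), length(sex))
}

# solve the aggregate (sum over member sites) so that the pipeline's estimate
# from `eq_id` reproduces the true BF%; sites are spread over the aggregate
# proportionally to `weights`
solve_aggregate <- function(bf_true, sex, age, eq_id, weights) {
  n <- length(bf_true)
  male <- as.numeric(sex == "male")
  if (eq_id == "evans7") {
    return((bf_true - 10.566 + 8.057 * male) / 0.12077)
  }
  if (eq_id == "evans3") {
    return((bf_true - 8.997 + 6.343 * male) / 0.24658)
  }
  row <- registry_lookup(eq_id)
  member <- generating_sites(eq_id, sex)
  vapply(seq_len(n), function(i) {
    mem <- member[[i]]
    w <- weights[mem] / sum(weights[mem])
    one <- function(agg) {
      sf <- stats::setNames(as.list(agg * weights / sum(weights[mem])),
                            sprintf("sf_%s_mm", names(weights)))
      df <- tibble::as_tibble(c(list(id = "x", sex = sex[i], age_y = age[i],
                                     mass_kg = 70, height_cm = 170,
                                     race_black = FALSE), sf))
      est <- if (row$predicts == "density_kg_per_L") {
        db <- density_value(df, eq_id, "corrected")
        (4.95 / db - 4.5) * 100
      } else {
        bf_value(df, eq_id)
      }
      est - bf_true[i]
    }
    lo <- suppressWarnings(one(0.5)); hi <- suppressWarnings(one(390))
    if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NA_real_)
    suppressWarnings(stats::uniroot(one, c(0.5, 390), tol = 1e-10)$root)
  }, numeric(1))
}

draw_batch <- function(n, sex, cfg) {
  male <- sex == "male"
  half <- cfg$bf_sex_offset / 2
  bf_mu <- ifelse(male, cfg$bf_mean - half, cfg$bf_mean + half)
  bf_sigma <- sqrt(max(cfg$bf_sd^2 - half^2, 0.25))

  age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd, cfg$age_range)
  height <- rtrunc_norm(n, cfg$height_mean, cfg$height_sd, cfg$height_range)
  bm <- rtrunc_norm(n, cfg$bm_mean, cfg$bm_sd, cfg$bm_range)
  bf <- rtrunc_norm(n, bf_mu, bf_sigma, cfg$bf_range)

  ffm <- bm * (1 - bf / 100)
  tbw <- cfg$hydration_ffm * ffm + stats::rnorm(n, 0, cfg$hydration_noise_sd)
  # density consistent with true BF% and true TBW under the 3C relation
  db <- 2.118 / (bf / 100 + 0.78 * (tbw / bm) + 1.354)
  # resistance solved from the Matias TBW relation at the true water volume
  denom <- tbw - 0.286 - 0.385 * bm - 5.086 * as.numeric(male)
  r_true <- 0.195 * height^2 / denom
  agg <- solve_aggregate(bf, sex, age, cfg$generating_equation,
                         cfg$site_weights)

  valid <- tbw > 0 & tbw < bm & db > 0.98 & db < 1.12 &
    denom > 0.5 & r_true > 100 & r_true < 1500 &
    !is.na(agg) & agg > 1 & agg < 390
  tibble::tibble(sex = sex, age_y = age, height_cm = height, mass_kg = bm,
                 bf_true = bf, ffm_true = ffm, tbw_true = tbw, db_true = db,
                 r_true = r_true, aggregate_mm = agg, valid = valid)
}

#' Generate a synthetic athlete cohort with known truth
#'
#' Draws a cohort whose measured columns have the statistical structure the
#' validation pipeline assumes, together with the per-athlete latent truth.
#' Per athlete: anthropometry from truncated normals; true fat-free mass from
#' the true body-fat percent; true total body water hydration-coupled to FFM
#' (fraction `hydration_ffm` plus biological noise); true density solved from
#' the Siri 3C relation at the true BF% and TBW, so the criterion model
#' recovers truth exactly when measurement noise is zero; resistance solved by
#' inverting the Matias TBW equation at the true water volume; skinfold site
#' values constructed by inverting the generating equation's aggregate at the
#' true BF%, spread across the 8 sites by `site_weights`, then perturbed by
#' site noise and split into 3 replicates with technician noise. Measured
#' `uww_db`, `adp_db`, `bis_tbw_l`, `r_ohm` add the configured device noise;
#' consumer-device BF% columns add configured bias and noise. Athletes whose
#' draw violates physiological bounds or defeats the equation inversion are
#' resampled up to `max_retries` times.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with `cohort` (a validated cohort
#'   tibble as [read_cohort()] returns) and `truth` (per-athlete `id`, `sex`,
#'   `bf_true_pct`, `ffm_true_kg`, `fm_true_kg`, `tbw_true_l`, `db_true_kgl`,
#'   `aggregate_mm`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sex <- c(rep("female", config$n_female), rep("male", config$n_male))
  n <- length(sex)
  if (n == 0L) stop("empty cohort requested", call. = FALSE)

  lat <- draw_batch(n, sex, config)
  tries <- 0L
  while (any(!lat$valid)) {
    tries <- tries + 1L
    if (tries > config$max_retries) {
      stop("athlete resampling failed after ", config$max_retries,
           " retries (equation inversion or physiological bounds)",
           call. = FALSE)
    }
    redo <- which(!lat$valid)
    lat[redo, ] <- draw_batch(length(redo), sex[redo], config)
  }

  id <- sprintf("ath%03d", seq_len(n))
  w <- config$site_weights[skinfold_sites()]
  member <- generating_sites(config$generating_equation, lat$sex)
  wsum_mem <- vapply(member, function(m) sum(w[m]), numeric(1))

  # noise-free site values: aggregate spread by weight, all 8 sites on the
  # same scale so the member sites sum exactly to the aggregate
  site_true <- outer(lat$aggregate_mm / wsum_mem, w)
  site_meas <- site_true +
    matrix(stats::rnorm(n * 8, 0, config$site_noise_sd), n, 8)
  site_meas <- pmin(pmax(site_meas, 0.2), 99)

  cohort <- tibble::tibble(
    id = id, sex = lat$sex, age_y = lat$age_y,
    height_cm = lat$height_cm, mass_kg = lat$mass_kg, race_black = FALSE)
  for (j in seq_along(skinfold_sites())) {
    for (rep_i in 1:3) {
      reading <- site_meas[, j] +
        stats::rnorm(n, 0, config$replicate_noise_sd)
      cohort[[sprintf("sf_%s_%d_mm", skinfold_sites()[j], rep_i)]] <-
        pmin(pmax(reading, 0.2), 99)
    }
  }
  cohort$r_ohm <- lat$r_true + stats::rnorm(n, 0, config$r_noise_sd)
  cohort$xc_ohm <- pmax(stats::rnorm(n, config$xc_mean, config$xc_sd), 1)
  cohort$uww_db <- lat$db_true + stats::rnorm(n, 0, config$db_noise_sd)
  cohort$adp_db <- lat$db_true + stats::rnorm(n, 0, config$adp_db_noise_sd)
  cohort$bis_tbw_l <- pmin(lat$tbw_true + stats::rnorm(n, 0, config$bis_tbw_noise_sd),
                           lat$mass_kg * 0.99)
  for (dev in config$devices) {
    bias <- config$device_bias[[dev]] %||% c(additive = 0, proportional = 0)
    cohort[[sprintf("bf_%s_pct", dev)]] <- pmax(
      lat$bf_true + bias[["additive"]] +
        bias[["proportional"]] * (lat$bf_true - config$bf_mean) +
        stats::rnorm(n, 0, config$device_bf_noise_sd), 0.5)
  }
  cohort <- reduce_triplicates(cohort)
  class(cohort) <- c("bc_cohort", class(cohort))

  truth <- tibble::tibble(
    id = id, sex = lat$sex,
    bf_true_pct = lat$bf_true,
    ffm_true_kg = lat$ffm_true,
    fm_true_kg = lat$mass_kg - lat$ffm_true,
    tbw_true_l = lat$tbw_true,
    db_true_kgl = lat$db_true,
    aggregate_mm = lat$aggregate_mm)

  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Inject proportional bias into a method's measurements
#'
#' Perturbs one method's measured quantity so that, against a noise-free
#' criterion, the Bland-Altman regression of (alternate - criterion) on the
#' per-athlete mean of the two methods has exactly the requested `slope`
#' (positive slope: the method increasingly overestimates in larger
#' athletes). The perturbation is applied on the fat-free-mass scale around
#' `anchor` (default: the cohort mean true FFM) and converted back to the
#' method's native quantity (BF% for device columns, litres for BIS water).
#'
#' @param records Cohort tibble from [generate_cohort()].
#' @param truth Matching truth tibble.
#' @param method A device name with a `bf_<method>_pct` column, or `"bis"`.
#' @param slope Target Bland-Altman slope (kg difference per kg mean).
#' @param anchor FFM anchor in kg.
#' @return The records tibble with the method's column perturbed.
#' @export
inject_proportional_bias <- function(records, truth, method, slope,
                                     anchor = NULL) {
  if (slope == 0) return(records)
  if (abs(slope) >= 2) stop("|slope| must be < 2", call. = FALSE)
  anchor <- anchor %||% mean(truth$ffm_true_kg)
  stopifnot(identical(records$id, truth$id))
  bias_ffm <- function(m0) {
    (m0 * (1 + slope / 2) - slope * anchor) / (1 - slope / 2)
  }
  col <- sprintf("bf_%s_pct", method)
  if (col %in% names(records)) {
    m0 <- records$mass_kg * (1 - records[[col]] / 100)
    records[[col]] <- 100 * (1 - bias_ffm(m0) / records$mass_kg)
  } else if (method == "bis") {
    h <- 0.732
    records$bis_tbw_l <- bias_ffm(records$bis_tbw_l / h) * h
  } else {
    stop("configuration error: unknown method '", method,
         "' for bias injection", call. = FALSE)
  }
  records
}
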