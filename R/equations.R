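# ---- sex / race coding tables (data, not branches) -------------------------
# Per-equation numeric codings. Conventions differ between sources:
# Matias/Evans code male = 1, Devrim-Lanpir codes female = 1. Race is coded
# 1 for Black/African American athletes where an equation uses it.
eq_sex_coding <- function() {
  tibble::tibble(
    eq_id  = c("evans3", "evans7", "matias_ffm", "matias_tbw", "devrim"),
    female = c(0,        0,        0,            0,            1),
    male   = c(1,        1,        1,            1,            0)
  )
}

sex_code <- function(eq_id, sex) {
  tab <- eq_sex_coding()
  row <- tab[tab$eq_id == eq_id, ]
  if (nrow(row) != 1L) stop("no sex coding defined for equation '", eq_id, "'")
  ifelse(sex == "male", row$male, row$female)
}

ss <- function(data, sites) {
  cols <- sprintf("sf_%s_mm", sites)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    return(rep(NA_real_, nrow(data)))
  }
  rowSums(as.matrix(data[cols]))
}

sf_col <- function(data, site) {
  col <- sprintf("sf_%s_mm", site)
  if (!col %in% names(data)) rep(NA_real_, nrow(data)) else data[[col]]
}

# ---- registry ---------------------------------------------------------------

#' Catalogue of prediction equations
#'
#' Machine-readable registry of every implemented prediction equation:
#' the classical skinfold body-density equations (Jackson & Pollock 3- and
#' 7-site, Forsyth, Katch, Lohman, Thorland, Durnin & Womersley), the direct
#' body-fat-percent equations (Evans 3- and 7-site, Slaughter, Loftin,
#' Devrim-Lanpir), the impedance/anthropometric fat-free-mass equations
#' (Matias, Stewart, Fornetti) and the Matias total-body-water equation.
#'
#' @return A tibble with one row per equation: `eq_id`, `predicts`
#'   (`"density_kg_per_L"`, `"bf_percent"`, `"ffm_kg"` or `"tbw_L"`),
#'   `applicable_sex` (list column), `required_sites` (list column),
#'   `needs_impedance`, `age_max` (`NA` when unrestricted) and `variants`
#'   (list column; equations with a printed-form ambiguity expose
#'   `"corrected"` and `"as_printed"`).
#' @export
equation_registry <- function() {
  t_ <- tibble::tibble
  reg <- t_(
    eq_id = c("jp3", "jp7", "forsyth", "katch", "lohman", "thorland", "dw",
              "evans3", "evans7", "slaughter", "loftin", "devrim",
              "matias_ffm", "stewart_ffm", "fornetti_ffm", "matias_tbw"),
    predicts = c(rep("density_kg_per_L", 7),
                 rep("bf_percent", 5),
                 rep("ffm_kg", 3), "tbw_L"),
    applicable_sex = list(
      c("female", "male"), c("female", "male"), c("female", "male"),
      c("female", "male"), c("female", "male"), c("female", "male"),
      c("female", "male"),
      c("female", "male"), c("female", "male"), "female", "female",
      c("female", "male"),
      c("female", "male"), "male", "female", c("female", "male")),
    required_sites = list(
      c("chest", "abdominal", "thigh", "triceps", "suprailiac"),  # jp3, sex-specific subset
      c("chest", "midaxillary", "triceps", "subscapular", "abdominal",
        "suprailiac", "thigh"),
      c("subscapular", "abdominal", "triceps", "midaxillary"),
      c("triceps", "subscapular", "abdominal"),
      c("triceps", "subscapular", "abdominal"),
      c("triceps", "subscapular", "midaxillary"),
      c("biceps", "triceps", "subscapular", "suprailiac"),
      c("abdominal", "thigh", "triceps"),
      c("chest", "midaxillary", "triceps", "subscapular", "abdominal",
        "suprailiac", "thigh"),
      c("triceps", "subscapular"),
      "triceps",
      "abdominal",
      character(), character(), character(), character()),
    needs_impedance = c(rep(FALSE, 12), TRUE, TRUE, FALSE, TRUE),
    age_max = c(NA, NA, NA, NA, NA, NA, 29,
                NA, NA, NA, NA, NA, NA, NA, NA, NA),
    variants = list(
      "as_printed", "as_printed", "as_printed", "as_printed", "as_printed",
      c("corrected", "as_printed"), "as_printed",
      "as_printed", "as_printed", "as_printed", "as_printed", "as_printed",
      "as_printed", c("corrected", "as_printed"), "as_printed", "as_printed")
  )
  reg
}

registry_lookup <- function(eq_id) {
  reg <- equation_registry()
  row <- reg[reg$eq_id == eq_id, ]
  if (nrow(row) != 1L) {
    stop("unknown equation id '", eq_id, "'; valid ids: ",
         paste(reg$eq_id, collapse = ", "), call. = FALSE)
  }
  row
}

# jp3's required sites depend on sex (chest/abdomen/thigh for males,
# triceps/thigh/suprailium for females)
jp3_sites <- function(sex) {
  lapply(sex, function(s) {
    if (identical(s, "male")) c("chest", "abdominal", "thigh")
    else c("triceps", "thigh", "suprailiac")
  })
}

# status helper: one status string per athlete given sex/age/site availability
eq_status <- function(data, eq_id) {
  row <- registry_lookup(eq_id)
  n <- nrow(data)
  status <- rep("ok", n)

  status[!data$sex %in% row$applicable_sex[[1]]] <- "not_applicable"

  if (eq_id == "jp3") {
    need <- jp3_sites(data$sex)
    miss <- vapply(seq_len(n), function(i) {
      any(is.na(vapply(need[[i]], function(s) sf_col(data, s)[i], 0)))
    }, logical(1))
  } else if (length(row$required_sites[[1]])) {
    m <- vapply(row$required_sites[[1]], function(s) sf_col(data, s), numeric(n))
    miss <- if (n == 1L) any(is.na(m)) else rowSums(is.na(m)) > 0
  } else {
    miss <- rep(FALSE, n)
  }
  if (eq_id == "loftin") {
    miss <- miss | is.na(data$mass_kg) | is.na(data$height_cm) | is.na(data$age_y)
  }
  if (isTRUE(row$needs_impedance)) {
    miss <- miss | is.na(data[["r_ohm"]] %||% rep(NA_real_, n))
    if (eq_id == "stewart_ffm") miss <- miss | is.na(data[["xc_ohm"]] %||% rep(NA_real_, n))
  }
  status[status == "ok" & miss] <- "not_computable"

  if (!is.na(row$age_max)) {
    status[status == "ok" & data$age_y > row$age_max] <- "out_of_stratum"
  }
  status
}

# ---- density equations ------------------------------------------------------

density_value <- function(data, eq_id, variant) {
  age <- data$age_y
  sexm <- data$sex == "male"
  switch(
    eq_id,
    jp3 = {
      s_m <- ss(data, c("chest", "abdominal", "thigh"))
      s_f <- ss(data, c("triceps", "thigh", "suprailiac"))
      ifelse(sexm,
             1.10938 - 0.0008267 * s_m + 0.0000016 * s_m^2 - 0.0002574 * age,
             1.0994921 - 0.0009929 * s_f + 0.0000023 * s_f^2 - 0.0001392 * age)
    },
    jp7 = {
      s <- ss(data, c("chest", "midaxillary", "triceps", "subscapular",
                      "abdominal", "suprailiac", "thigh"))
      ifelse(sexm,
             1.112 - 0.00043499 * s + 0.00000055 * s^2 - 0.00028826 * age,
             1.0970 - 0.00046971 * s + 0.00000056 * s^2 - 0.00012828 * age)
    },
    forsyth = 1.10647 - 0.00162 * sf_col(data, "subscapular") -
      0.00144 * sf_col(data, "abdominal") -
      0.00077 * sf_col(data, "triceps") +
      0.00071 * sf_col(data, "midaxillary"),
    katch = 1.09665 - 0.00103 * sf_col(data, "triceps") -
      0.00056 * sf_col(data, "subscapular") -
      0.00054 * sf_col(data, "abdominal"),
    lohman = {
      s <- ss(data, c("triceps", "subscapular", "abdominal"))
      1.0982 - 0.000815 * s + 0.00000084 * s^2
    },
    thorland = {
      s <- ss(data, c("triceps", "subscapular", "midaxillary"))
      lin <- if (identical(variant, "as_printed")) {
        sf_col(data, "triceps") * sf_col(data, "subscapular") *
          sf_col(data, "midaxillary")
      } else {
        s
      }
      1.1136 - 0.00154 * lin + 0.00000516 * s^2
    },
    dw = {
      s4 <- ss(data, c("biceps", "triceps", "subscapular", "suprailiac"))
      young <- age <= 19
      if (any(age < 16 & data$sex == "female", na.rm = TRUE) ||
          any(age < 17 & data$sex == "male", na.rm = TRUE)) {
        warning("Durnin & Womersley applied below its youngest published ",
                "stratum for some athletes", call. = FALSE)
      }
      c_ <- ifelse(sexm, ifelse(young, 1.1620, 1.1631),
                   ifelse(young, 1.1549, 1.1599))
      m_ <- ifelse(sexm, ifelse(young, 0.0630, 0.0632),
                   ifelse(young, 0.0678, 0.0717))
      c_ - m_ * log10(s4)
    },
    stop("equation '", eq_id, "' does not predict body density", call. = FALSE)
  )
}

#' Estimate body density from a skinfold equation
#'
#' Applies one of the Table-of-equations skinfold regressions to every athlete
#' in a cohort. Athletes of a non-applicable sex get status
#' `"not_applicable"`, athletes missing a required site `"not_computable"`,
#' and athletes above an equation's age stratum (Durnin & Womersley, > 29 y)
#' `"out_of_stratum"`; their density is `NA`. Densities outside
#' (0.98, 1.12) kg/L are flagged `nonphysical` but retained.
#'
#' The Durnin & Womersley log is base 10 (the original publication's
#' convention). Thorland's printed linear term multiplies the three sites;
#' the default `"corrected"` variant sums them (consistent with its squared
#' term); `"as_printed"` evaluates the product literally.
#'
#' @param data A cohort tibble (with replicate-averaged `sf_<site>_mm`
#'   columns; see [reduce_triplicates()]).
#' @param eq_id One of the density equation ids in [equation_registry()]:
#'   `"jp3"`, `"jp7"`, `"forsyth"`, `"katch"`, `"lohman"`, `"thorland"`,
#'   `"dw"`.
#' @param variant `"corrected"` (default) or `"as_printed"`; only Thorland
#'   distinguishes the two.
#' @return Tibble with columns `id`, `method_id`, `db` (kg/L), `status`,
#'   `nonphysical`.
#' @export
estimate_density <- function(data, eq_id, variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  row <- registry_lookup(eq_id)
  if (row$predicts != "density_kg_per_L") {
    stop("equation '", eq_id, "' predicts ", row$predicts,
         ", not body density", call. = FALSE)
  }
  status <- eq_status(data, eq_id)
  db <- density_value(data, eq_id, variant)
  db[status != "ok"] <- NA_real_
  tibble::tibble(
    id = data$id,
    method_id = eq_id,
    db = db,
    status = status,
    nonphysical = !is.na(db) & (db <= 0.98 | db >= 1.12)
  )
}

# ---- direct body-fat equations ---------------------------------------------

bf_value <- function(data, eq_id) {
  race <- as.numeric(data[["race_black"]] %||% rep(FALSE, nrow(data)))
  switch(
    eq_id,
    evans3 = 8.997 + 0.24658 * ss(data, c("abdominal", "thigh", "triceps")) -
      6.343 * sex_code("evans3", data$sex) - 1.998 * race,
    evans7 = 10.566 + 0.12077 * ss(data, c("chest", "midaxillary", "triceps",
                                           "subscapular", "abdominal",
                                           "suprailiac", "thigh")) -
      8.057 * sex_code("evans7", data$sex) - 2.545 * race,
    slaughter = {
      s <- ss(data, c("triceps", "subscapular"))
      ifelse(s <= 35,
             0.546 * s + 9.7,
             1.33 * s - 0.013 * s^2 - 2.4)
    },
    loftin = {
      bmi <- data$mass_kg / (data$height_cm / 100)^2
      tri <- sf_col(data, "triceps")
      -23.39 + 2.27 * bmi + 1.94 * tri - 2.95 * race -
        0.52 * data$age_y - 0.06 * bmi * tri
    },
    devrim = 0.30 + 0.72 * sf_col(data, "abdominal") +
      11.43 * sex_code("devrim", data$sex),
    stop("equation '", eq_id, "' does not predict body fat percent",
         call. = FALSE)
  )
}

#' Estimate body-fat percent from a direct anthropometric equation
#'
#' Direct BF% regressions: Evans 3- and 7-site (male = 1, race Black = 1),
#' Slaughter (females; branches at a 35 mm triceps+subscapular sum), Loftin
#' (females; uses BMI), Devrim-Lanpir (female = 1). Statuses as in
#' [estimate_density()].
#'
#' @inheritParams estimate_density
#' @param eq_id `"evans3"`, `"evans7"`, `"slaughter"`, `"loftin"` or
#'   `"devrim"`.
#' @return Tibble with columns `id`, `method_id`, `bf_percent`, `status`.
#' @export
estimate_bf_direct <- function(data, eq_id) {
  row <- registry_lookup(eq_id)
  if (row$predicts != "bf_percent") {
    stop("equation '", eq_id, "' predicts ", row$predicts,
         ", not body fat percent", call. = FALSE)
  }
  status <- eq_status(data, eq_id)
  bf <- bf_value(data, eq_id)
  bf[status != "ok"] <- NA_real_
  tibble::tibble(id = data$id, method_id = eq_id,
                 bf_percent = bf, status = status)
}

# ---- fat-free mass equations -----------------------------------------------

#' Estimate fat-free mass from impedance or anthropometry
#'
#' Matias (resistance index height_cm^2/R, male = 1), Stewart (males only,
#' height in metres) and Fornetti (females only, height in cm).
#'
#' Stewart's printed coefficients ("662.7 x BM") yield fat-free mass far in
#' excess of body mass for any athlete; the default `"corrected"` variant
#' scales the body-mass, reactance and intercept coefficients by 10^-3
#' (0.6627 BM + 0.0718 Xc + 0.6627), keeping the kilogram-scale
#' 294.3 height_m^2/R term as printed. `"as_printed"` evaluates the printed
#' coefficients literally; its output is flagged `nonphysical` whenever FFM
#' exceeds body mass.
#'
#' @inheritParams estimate_density
#' @param eq_id `"matias_ffm"`, `"stewart_ffm"` or `"fornetti_ffm"`.
#' @param variant `"corrected"` (default) or `"as_printed"`; only Stewart
#'   distinguishes the two.
#' @return Tibble with columns `id`, `method_id`, `ffm` (kg), `status`,
#'   `nonphysical` (FFM outside (0, body mass)).
#' @export
estimate_ffm_direct <- function(data, eq_id,
                                variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  row <- registry_lookup(eq_id)
  if (row$predicts != "ffm_kg") {
    stop("equation '", eq_id, "' predicts ", row$predicts,
         ", not fat-free mass", call. = FALSE)
  }
  status <- eq_status(data, eq_id)
  n <- nrow(data)
  r <- data[["r_ohm"]] %||% rep(NA_real_, n)
  xc <- data[["xc_ohm"]] %||% rep(NA_real_, n)
  ffm <- switch(
    eq_id,
    matias_ffm = -2.261 + 0.327 * (data$height_cm^2 / r) +
      0.525 * data$mass_kg + 5.462 * sex_code("matias_ffm", data$sex),
    stewart_ffm = {
      ht_m <- data$height_cm / 100
      if (identical(variant, "as_printed")) {
        294.3 * (ht_m^2 / r) + 662.7 * data$mass_kg + 71.8 * xc + 662.7
      } else {
        294.3 * (ht_m^2 / r) + 0.6627 * data$mass_kg + 0.0718 * xc + 0.6627
      }
    },
    fornetti_ffm = 0.143 * data$height_cm + 0.565 * data$mass_kg - 10.03
  )
  ffm[status != "ok"] <- NA_real_
  tibble::tibble(id = data$id, method_id = eq_id, ffm = ffm, status = status,
                 nonphysical = !is.na(ffm) & (ffm <= 0 | ffm > data$mass_kg))
}

#' Estimate total body water from single-frequency resistance (Matias)
#'
#' TBW (L) = 0.286 + 0.195 height_cm^2/R + 0.385 BM + 5.086 sex (male = 1).
#' This is the total-body-water source of the field three-compartment model.
#'
#' @inheritParams estimate_density
#' @return Tibble with columns `id`, `method_id` (`"matias_tbw"`), `tbw_l`,
#'   `status`.
#' @export
estimate_tbw_matias <- function(data) {
  status <- eq_status(data, "matias_tbw")
  r <- data[["r_ohm"]] %||% rep(NA_real_, nrow(data))
  tbw <- 0.286 + 0.195 * (data$height_cm^2 / r) + 0.385 * data$mass_kg +
    5.086 * sex_code("matias_tbw", data$sex)
  tbw[status != "ok"] <- NA_real_
  tibble::tibble(id = data$id, method_id = "matias_tbw",
                 tbw_l = tbw, status = status)
}

#' Residual lung volume by closed-circuit oxygen dilution (Wilmore)
#'
#' RV = VO2 (EN - IN) / \[AN - FN - RVDS\] with mouthpiece dead space
#' RVDS = 0.070 L, evaluated literally as printed (`"as_printed"`, default).
#' The printed bracket subtracts a volume (litres) from a percentage
#' difference; the `"dead_space_subtracted"` variant instead computes
#' VO2 (EN - IN)/(AN - FN) - RVDS, placing the dead-space correction on the
#' volume scale. Both are exposed because the intended placement is ambiguous.
#'
#' @param vo2 Initial O2 volume in the spirometer system (L), > 0.
#' @param en Percent nitrogen at equilibrium.
#' @param i_n Percent nitrogen impurity.
#' @param an Percent alveolar nitrogen.
#' @param fn Percent final nitrogen.
#' @param variant `"as_printed"` or `"dead_space_subtracted"`.
#' @return Residual volume in litres.
#' @export
residual_volume_wilmore <- function(vo2, en, i_n, an, fn,
                                    variant = c("as_printed",
                                                "dead_space_subtracted")) {
  variant <- match.arg(variant)
  stopifnot(all(vo2 > 0))
  pct <- c(en, i_n, an, fn)
  if (any(pct < 0 | pct > 100)) {
    stop("nitrogen fractions must be percentages in [0, 100]", call. = FALSE)
  }
  rvds <- 0.070
  denom <- if (variant == "as_printed") an - fn - rvds else an - fn
  if (any(denom <= 0)) {
    stop("degenerate input: nonpositive denominator AN - FN", call. = FALSE)
  }
  rv <- vo2 * (en - i_n) / denom
  if (variant == "dead_space_subtracted") rv <- rv - rvds
  rv
}
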