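#' Roster of body-composition methods
#'
#' Every method the validation pipeline can compute, in the conventional
#' reporting order: the criterion 3C model, the field 3C model, ADP and UWW
#' densitometry under Brozek and Siri conversions, the anthropometric and
#' impedance FFM equations, consumer-device outputs, spectroscopy water, and
#' the skinfold equations (density equations converted with Siri 2C, direct
#' BF% equations composed to FFM).
#'
#' @return Tibble with `method_id`, `label`, `group`.
#' @export
method_catalog <- function() {
  tibble::tibble(
    method_id = c("criterion_3c", "field_3c", "adp_brozek", "adp_siri",
                  "fornetti_ffm", "mfbia", "matias_ffm", "stewart_ffm",
                  "f2fbia", "bis",
                  "skf_devrim", "skf_dw", "skf_evans3", "skf_evans7",
                  "skf_forsyth", "skf_jp3", "skf_jp7", "skf_katch",
                  "skf_loftin", "skf_lohman", "skf_slaughter", "skf_thorland",
                  "uww_brozek", "uww_siri"),
    label = c("3C", "3C Field", "ADP (Brozek)", "ADP (Siri)",
              "Anthro (F)", "MFBIA (InBody)", "SFBIA (RJL/Matias)",
              "SFBIA (RJL/Stewart)", "F2FBIA (Tanita)", "BIS",
              "SKF (DL)", "SKF (DW)", "SKF (Ev.3)", "SKF (Ev.7)",
              "SKF (Forsyth)", "SKF (JP3)", "SKF (JP7)", "SKF (Katch)",
              "SKF (Loftin)", "SKF (Lohman)", "SKF (Slaughter)",
              "SKF (Thorland)", "UWW (Brozek)", "UWW (Siri)"),
    group = c("criterion", "3c", "adp", "adp", "anthro", "device",
              "impedance_eq", "impedance_eq", "device", "bis",
              rep("skf", 12), "uww", "uww")
  )
}

skf_density_eqs <- function() c(dw = "skf_dw", forsyth = "skf_forsyth",
                                jp3 = "skf_jp3", jp7 = "skf_jp7",
                                katch = "skf_katch", lohman = "skf_lohman",
                                thorland = "skf_thorland")
skf_bf_eqs <- function() c(devrim = "skf_devrim", evans3 = "skf_evans3",
                           evans7 = "skf_evans7", loftin = "skf_loftin",
                           slaughter = "skf_slaughter")

siri_or_na <- function(db) ifelse(!is.na(db) & db > 0, (4.95 / db - 4.5) * 100,
                                  NA_real_)
brozek_or_na <- function(db) ifelse(!is.na(db) & db > 0,
                                    (4.57 / db - 4.142) * 100, NA_real_)

density_method <- function(data, method_id, db, convert) {
  bf <- convert(db)
  out <- compose_estimate(method_id, bf, data$mass_kg, id = data$id, db = db)
  out$status <- ifelse(is.na(bf), "not_computable", "ok")
  out
}

#' Per-athlete composition estimates under every method
#'
#' Runs the whole method roster over a cohort and returns one long tidy table
#' of composition estimates. Skinfold density equations are converted with
#' the Siri 2C equation; UWW and ADP densities with both Siri and Brozek;
#' impedance FFM equations and device BF% columns are composed directly;
#' spectroscopy FFM is `bis_tbw_l / 0.732` (the criterion hydration
#' constant). Methods not computable for an athlete carry `NA` estimates and
#' an explanatory `status`.
#'
#' @param data A cohort tibble.
#' @param field3c_skf Skinfold equation feeding the field 3C model.
#' @param variant Equation variant (see [estimate_density()]).
#' @return Long tibble: `id`, `sex`, `method_id`, `db`, `bf_percent`, `ffm`,
#'   `fm`, `implausible`, `status`.
#' @export
estimate_all <- function(data, field3c_skf = "jp7",
                         variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  n <- nrow(data)
  na_col <- rep(NA_real_, n)
  out <- list()

  out$criterion_3c <- criterion_3c(data)
  out$field_3c <- field_3c(data, skf_eq_id = field3c_skf, variant = variant)

  for (src in c("uww", "adp")) {
    db <- data[[paste0(src, "_db")]] %||% na_col
    out[[paste0(src, "_siri")]] <-
      density_method(data, paste0(src, "_siri"), db, siri_or_na)
    out[[paste0(src, "_brozek")]] <-
      density_method(data, paste0(src, "_brozek"), db, brozek_or_na)
  }

  for (eq in names(skf_density_eqs())) {
    dens <- estimate_density(data, eq, variant = variant)
    bf <- siri_or_na(dens$db)
    est <- compose_estimate(skf_density_eqs()[[eq]], bf, data$mass_kg,
                            id = data$id, db = dens$db)
    est$status <- ifelse(dens$status != "ok", dens$status,
                         ifelse(is.na(bf), "not_computable", "ok"))
    out[[skf_density_eqs()[[eq]]]] <- est
  }

  for (eq in names(skf_bf_eqs())) {
    bfd <- estimate_bf_direct(data, eq)
    est <- compose_estimate(skf_bf_eqs()[[eq]], bfd$bf_percent, data$mass_kg,
                            id = data$id)
    est$status <- bfd$status
    out[[skf_bf_eqs()[[eq]]]] <- est
  }

  for (eq in c("matias_ffm", "stewart_ffm", "fornetti_ffm")) {
    ffm <- estimate_ffm_direct(data, eq, variant = variant)
    bf <- 100 * (1 - ffm$ffm / data$mass_kg)
    est <- compose_estimate(eq, bf, data$mass_kg, id = data$id)
    est$status <- ffm$status
    out[[eq]] <- est
  }

  tbw <- data$bis_tbw_l %||% na_col
  bis_ffm <- tbw / 0.732
  bis_bf <- 100 * (1 - bis_ffm / data$mass_kg)
  est <- compose_estimate("bis", bis_bf, data$mass_kg, id = data$id)
  est$status <- ifelse(is.na(tbw), "not_computable", "ok")
  out$bis <- est

  for (col in grep("^bf_.*_pct$", names(data), value = TRUE)) {
    dev <- sub("^bf_(.*)_pct$", "\\1", col)
    est <- compose_estimate(dev, data[[col]], data$mass_kg, id = data$id)
    est$status <- ifelse(is.na(data[[col]]), "not_computable", "ok")
    out[[dev]] <- est
  }

  long <- dplyr::bind_rows(out)
  long <- dplyr::left_join(long,
                           dplyr::select(tibble::as_tibble(data), "id", "sex"),
                           by = "id")
  dplyr::relocate(long, "id", "sex", "method_id")
}

default_weight_classes <- function() {
  list(female = weight_class_table(45.4, 5.4, 14),
       male = weight_class_table(48.0, 5.4, 14))
}

#' Run the full cross-validation pipeline
#'
#' For each sex stratum (or the pooled cohort) and each computable method:
#' per-athlete composition estimates, the full agreement report against the
#' criterion (mean difference, limits of agreement, proportional-bias
#' regression, Pearson r, Lin's CCC, SEE, paired TOST at `margin_kg`), the
#' repeated-measures ANOVA across methods with Holm-adjusted follow-ups
#' against the criterion, minimum wrestling weights with weight-class
#' assignment, and the criterion-vs-method mis-categorization accounting.
#' Methods with fewer than 3 computable athletes in a stratum are reported as
#' absent for that stratum (mirroring female-only / male-only equations).
#'
#' @param data A cohort tibble ([read_cohort()] or
#'   [generate_cohort()]`$cohort`).
#' @param criterion Criterion method id (default `"criterion_3c"`).
#' @param field3c_skf Skinfold equation feeding the field 3C model
#'   (default `"jp7"`).
#' @param margin_kg TOST equivalence margin (default 2 kg).
#' @param alpha Significance level (default 0.05).
#' @param by_sex Stratify by sex (default) or pool.
#' @param methods Optional subset of method ids to validate.
#' @param weight_classes Named list of per-sex class ladders (upper limits in
#'   kg); default an evenly spaced 5.4 kg ladder per sex.
#' @param wc_round_to Optional MWW rounding increment before class lookup.
#' @return An object of class `validation_run`: a list with `estimates`,
#'   `agreement`, `anova`, `mww`, `miscategorization`, `config`.
#'   [generics::tidy()] returns the agreement table, [generics::glance()] a
#'   one-row run summary, and [render_table2()] the means-and-differences
#'   summary table.
#' @export
run_validation <- function(data, criterion = "criterion_3c",
                           field3c_skf = "jp7", margin_kg = 2, alpha = 0.05,
                           by_sex = TRUE, methods = NULL,
                           weight_classes = default_weight_classes(),
                           wc_round_to = NULL) {
  stopifnot(margin_kg > 0)
  est <- estimate_all(data, field3c_skf = field3c_skf)
  if (!is.null(methods)) {
    est <- est[est$method_id %in% union(methods, criterion), ]
  }
  if (!any(est$method_id == criterion & est$status == "ok")) {
    stop("criterion method '", criterion,
         "' is not computable for any athlete", call. = FALSE)
  }
  est$stratum <- if (by_sex) est$sex else "pooled"

  agreement <- list(); anova <- list(); mww_rows <- list(); miscat <- list()
  for (str in unique(est$stratum)) {
    stratum_est <- est[est$stratum == str, ]
    n_ath <- length(unique(stratum_est$id))
    if (n_ath < 3) {
      stop("insufficient data: stratum '", str, "' has ", n_ath,
           " athlete(s); need >= 3", call. = FALSE)
    }
    crit <- stratum_est[stratum_est$method_id == criterion &
                          stratum_est$status == "ok", c("id", "ffm")]
    names(crit)[2] <- "criterion"

    alt_ids <- setdiff(unique(stratum_est$method_id), criterion)
    rows <- list()
    for (m in alt_ids) {
      alt <- stratum_est[stratum_est$method_id == m &
                           stratum_est$status == "ok", c("id", "ffm")]
      names(alt)[2] <- "alternate"
      paired <- dplyr::inner_join(crit, alt, by = "id")
      paired <- paired[stats::complete.cases(paired), ]
      if (nrow(paired) < 3) next  # absent for this stratum
      rows[[m]] <- agreement_report(paired, method_id = m,
                                    margin = margin_kg, alpha = alpha)
    }
    agr <- dplyr::bind_rows(rows)

    # RM-ANOVA family: listwise-complete athletes across present methods
    present <- c(criterion, names(rows))
    fam <- stratum_est[stratum_est$method_id %in% present &
                         stratum_est$status == "ok" & !is.na(stratum_est$ffm),
                       c("id", "method_id", "ffm")]
    an <- rm_anova_holm(fam, value = "ffm", method = "method_id", id = "id",
                        reference = criterion)
    agr <- dplyr::left_join(
      agr, dplyr::select(an$contrasts, method_id = "method", holm = "p_holm"),
      by = "method_id")
    agr$holm_p <- agr$holm
    agr$holm <- NULL
    agr$stratum <- str
    agreement[[str]] <- dplyr::relocate(agr, "stratum")
    anova[[str]] <- dplyr::mutate(an$anova, stratum = str, .before = 1)

    # minimum wrestling weight + weight classes
    ladder <- if (by_sex) weight_classes[[str]] else weight_classes[["male"]]
    ok_est <- stratum_est[stratum_est$status == "ok" &
                            !is.na(stratum_est$bf_percent), ]
    sex_of <- stats::setNames(data$sex, data$id)
    mww_tbl <- dplyr::mutate(
      ok_est[, c("id", "method_id", "bf_percent")],
      bm = stats::setNames(data$mass_kg, data$id)[.data$id],
      mww = minimum_wrestling_weight(.data$bm, .data$bf_percent,
                                     sex_of[.data$id]),
      weight_class = suppressWarnings(
        assign_weight_class(.data$mww, ladder, round_to = wc_round_to)),
      stratum = str)
    mww_rows[[str]] <- dplyr::select(mww_tbl, "stratum", "id", "method_id",
                                     "mww", "weight_class")
    crit_mww <- mww_rows[[str]][mww_rows[[str]]$method_id == criterion, ]
    mc <- purrr::map_dfr(names(rows), function(m) {
      alt_mww <- mww_rows[[str]][mww_rows[[str]]$method_id == m, ]
      shared <- intersect(crit_mww$id, alt_mww$id)
      s <- miscategorization_summary(
        crit_mww[crit_mww$id %in% shared, ],
        alt_mww[alt_mww$id %in% shared, ])
      dplyr::mutate(s, stratum = str, method_id = m, .before = 1)
    })
    miscat[[str]] <- mc
  }

  structure(list(
    estimates = est,
    agreement = dplyr::bind_rows(agreement),
    anova = dplyr::bind_rows(anova),
    mww = dplyr::bind_rows(mww_rows),
    miscategorization = dplyr::bind_rows(miscat),
    config = list(criterion = criterion, field3c_skf = field3c_skf,
                  margin_kg = margin_kg, alpha = alpha, by_sex = by_sex,
                  weight_classes = weight_classes)
  ), class = "validation_run")
}

#' Render the means-and-differences summary table
#'
#' The machine version of the classic per-method summary: for each stratum
#' and each roster method, the method's FFM mean and SD and the mean
#' difference from the criterion with its SD. Method/stratum combinations
#' that are not computable (female-only or male-only equations) appear as
#' explicit `NA` rows, and the criterion row carries no difference columns.
#'
#' @param run A `validation_run`.
#' @param digits Rounding for the rendered values (default 1 decimal, the
#'   conventional reporting precision); `NULL` for full precision.
#' @return Tibble: `stratum`, `method_id`, `label`, `mean_kg`, `sd_kg`,
#'   `md_kg`, `sd_md_kg`.
#' @export
render_table2 <- function(run, digits = 1) {
  stopifnot(inherits(run, "validation_run"))
  cat_tbl <- method_catalog()
  strata <- unique(run$estimates$stratum)
  grid <- tidyr::expand_grid(stratum = strata,
                             method_id = cat_tbl$method_id)
  means <- run$estimates |>
    dplyr::filter(.data$status == "ok", !is.na(.data$ffm)) |>
    dplyr::group_by(.data$stratum, .data$method_id) |>
    dplyr::summarise(mean_kg = mean(.data$ffm), sd_kg = stats::sd(.data$ffm),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= 3) |>
    dplyr::select(-"n")
  diffs <- dplyr::select(run$agreement, "stratum", "method_id",
                         md_kg = "mean_diff", sd_md_kg = "sd_diff")
  out <- grid |>
    dplyr::left_join(cat_tbl[, c("method_id", "label")], by = "method_id") |>
    dplyr::left_join(means, by = c("stratum", "method_id")) |>
    dplyr::left_join(diffs, by = c("stratum", "method_id")) |>
    dplyr::filter(!is.na(.data$mean_kg) |
                    .data$method_id %in% unique(run$estimates$method_id))
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("mean_kg", "sd_kg", "md_kg", "sd_md_kg"), ~ round(.x, digits)))
  }
  out
}
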