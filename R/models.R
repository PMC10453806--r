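#' Two- and three-compartment body-fat conversions
#'
#' Convert whole-body density (and, for the 3C model, total body water) into
#' body-fat percent:
#' \itemize{
#'   \item Siri 2C: BF% = (4.95 / Db - 4.5) x 100
#'   \item Brozek 2C: BF% = (4.57 / Db - 4.142) x 100
#'   \item Siri 3C: BF% = 100 x (2.118 / Db - 0.78 x TBW/BM - 1.354)
#' }
#' All three are vectorised. The 3C model corrects densitometric body fat for
#' inter-individual hydration differences; TBW in litres is treated as
#' numerically equal to kg of water.
#'
#' @param db Body density in kg/L, > 0.
#' @param tbw Total body water in litres, 0 < tbw < bm.
#' @param bm Body mass in kg.
#' @return Body-fat percent.
#' @examples
#' siri_2c(1.1)            # 0
#' brozek_2c(4.57 / 4.142) # 0
#' siri_3c(1.05, 42, 70)
#' @export
siri_2c <- function(db) {
  if (any(db <= 0)) stop("degenerate input: body density must be > 0", call. = FALSE)
  (4.95 / db - 4.5) * 100
}

#' @rdname siri_2c
#' @export
brozek_2c <- function(db) {
  if (any(db <= 0)) stop("degenerate input: body density must be > 0", call. = FALSE)
  (4.57 / db - 4.142) * 100
}

#' @rdname siri_2c
#' @export
siri_3c <- function(db, tbw, bm) {
  if (any(db <= 0)) stop("degenerate input: body density must be > 0", call. = FALSE)
  ok <- is.na(tbw) | is.na(bm) | (tbw > 0 & tbw < bm)
  if (!all(ok)) {
    stop("degenerate input: total body water must lie in (0, body mass)",
         call. = FALSE)
  }
  100 * (2.118 / db - 0.78 * (tbw / bm) - 1.354)
}

#' Assemble a composition estimate from body-fat percent
#'
#' Splits body mass into fat and fat-free mass: FFM = BM (1 - BF%/100),
#' FM = BM - FFM, so FM + FFM = BM exactly. Body-fat values outside
#' \[0, 60\]% are flagged `implausible` but retained.
#'
#' @param method_id Method label carried into the output.
#' @param bf_percent Body-fat percent (vector).
#' @param bm Body mass in kg, > 0.
#' @param id Optional athlete ids.
#' @param db Optional body density column carried through.
#' @return Tibble with columns `id`, `method_id`, `db`, `bf_percent`, `ffm`,
#'   `fm`, `implausible`.
#' @export
compose_estimate <- function(method_id, bf_percent, bm, id = NULL, db = NULL) {
  if (any(bm <= 0, na.rm = TRUE)) stop("body mass must be > 0", call. = FALSE)
  n <- max(length(bf_percent), length(bm))
  ffm <- bm * (1 - bf_percent / 100)
  tibble::tibble(
    id = id %||% as.character(seq_len(n)),
    method_id = method_id,
    db = db %||% rep(NA_real_, n),
    bf_percent = bf_percent,
    ffm = ffm,
    fm = bm - ffm,
    implausible = !is.na(bf_percent) & (bf_percent < 0 | bf_percent > 60)
  )
}

#' Criterion and field three-compartment estimates
#'
#' `criterion_3c()` is the reference configuration: density from underwater
#' weighing (`uww_db`), total body water from bioimpedance spectroscopy
#' (`bis_tbw_l`), body mass from the scale, combined with the Siri 3C model.
#' `field_3c()` replaces both laboratory inputs with field measures: density
#' from a skinfold equation and TBW from the Matias single-frequency
#' resistance equation. Athletes missing a required input are returned with
#' `status = "not_computable"` and `NA` estimates (they are excluded from
#' comparisons downstream, never silently dropped).
#'
#' @param data A cohort tibble.
#' @param skf_eq_id Skinfold density equation feeding the field model
#'   (default `"jp7"`).
#' @param variant Variant passed to [estimate_density()].
#' @return Tibble as [compose_estimate()] plus a `status` column.
#' @export
criterion_3c <- function(data) {
  n <- nrow(data)
  db <- data[["uww_db"]] %||% rep(NA_real_, n)
  tbw <- data[["bis_tbw_l"]] %||% rep(NA_real_, n)
  ok <- !is.na(db) & !is.na(tbw) & !is.na(data$mass_kg)
  bf <- rep(NA_real_, n)
  bf[ok] <- siri_3c(db[ok], tbw[ok], data$mass_kg[ok])
  out <- compose_estimate("criterion_3c", bf, data$mass_kg,
                          id = data$id, db = db)
  out$status <- ifelse(ok, "ok", "not_computable")
  out
}

#' @rdname criterion_3c
#' @export
field_3c <- function(data, skf_eq_id = "jp7",
                     variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  dens <- estimate_density(data, skf_eq_id, variant = variant)
  tbw <- estimate_tbw_matias(data)
  ok <- dens$status == "ok" & tbw$status == "ok" & !is.na(data$mass_kg) &
    !is.na(dens$db) & tbw$tbw_l > 0 & tbw$tbw_l < data$mass_kg
  ok[is.na(ok)] <- FALSE
  bf <- rep(NA_real_, nrow(data))
  bf[ok] <- siri_3c(dens$db[ok], tbw$tbw_l[ok], data$mass_kg[ok])
  out <- compose_estimate("field_3c", bf, data$mass_kg,
                          id = data$id, db = dens$db)
  out$status <- ifelse(ok, "ok", "not_computable")
  out
}
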