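#' The eight-site skinfold model
#'
#' Site names, in measurement order, for the 8-site caliper protocol
#' (subscapular, triceps, chest, midaxillary, suprailiac, abdominal, thigh,
#' biceps). All skinfold columns in a cohort table are named
#' `sf_<site>_<rep>_mm` for raw replicate readings and `sf_<site>_mm` for the
#' replicate-averaged value.
#'
#' @return Character vector of the eight site names.
#' @export
skinfold_sites <- function() {
  c("subscapular", "triceps", "chest", "midaxillary",
    "suprailiac", "abdominal", "thigh", "biceps")
}

# canonical column names for a cohort table
cohort_mandatory_cols <- function() c("id", "sex", "age_y", "height_cm", "mass_kg")

cohort_replicate_cols <- function() {
  sites <- skinfold_sites()
  as.vector(t(outer(sites, 1:3, function(s, r) sprintf("sf_%s_%d_mm", s, r))))
}

cohort_reduced_cols <- function() sprintf("sf_%s_mm", skinfold_sites())

cohort_optional_cols <- function() {
  c("race_black", cohort_replicate_cols(), cohort_reduced_cols(),
    "r_ohm", "xc_ohm", "uww_db", "adp_db", "bis_tbw_l")
}

parse_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("female", "f", "0")] <- "female"
  out[lx %in% c("male", "m", "1")] <- "male"
  out
}

as_num <- function(x) suppressWarnings(as.numeric(x))

#' Read and validate an athlete cohort from CSV
#'
#' Reads a delimited file of per-athlete measurements into a validated cohort
#' tibble. Mandatory columns are `id`, `sex`, `age_y`, `height_cm`, `mass_kg`
#' (after alias mapping); all other canonical columns — `race_black`, the
#' 24 skinfold replicate columns `sf_<site>_<rep>_mm`, impedance `r_ohm` /
#' `xc_ohm`, densitometry `uww_db` / `adp_db`, `bis_tbw_l`, and any
#' device body-fat columns `bf_<device>_pct` — are optional. Rows that fail
#' validation are dropped and reported in the `rejections` attribute (also
#' retrievable with [cohort_rejections()]), naming the row and the offending
#' field. Heights between 1.2 and 2.3 are interpreted as metres and converted
#' to centimetres when `autoconvert_units = TRUE`.
#'
#' @param path Path to a CSV file.
#' @param aliases Named character vector mapping file header names to
#'   canonical column names, e.g. `c(weight = "mass_kg")`.
#' @param autoconvert_units Convert metre-scale heights to cm? Default `FALSE`.
#' @param reduce Average skinfold replicates into `sf_<site>_mm` columns on
#'   read (see [reduce_triplicates()])? Default `TRUE`.
#' @return A tibble with one validated row per athlete, classed
#'   `bc_cohort`, with a `rejections` attribute tibble
#'   (`row`, `id`, `field`, `reason`).
#' @seealso [write_cohort()], [reduce_triplicates()], [generate_cohort()]
#' @export
read_cohort <- function(path, aliases = NULL, autoconvert_units = FALSE,
                        reduce = TRUE) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  missing_mand <- setdiff(cohort_mandatory_cols(), names(raw))
  if (length(missing_mand)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  }
  validate_cohort(tibble::as_tibble(raw), autoconvert_units = autoconvert_units,
                  reduce = reduce)
}

#' @rdname read_cohort
#' @param cohort A data frame of raw (character or numeric) cohort columns.
#' @export
validate_cohort <- function(cohort, autoconvert_units = FALSE, reduce = TRUE) {
  rej <- list()
  reject <- function(row, id, field, reason) {
    rej[[length(rej) + 1L]] <<- tibble::tibble(
      row = row, id = id, field = field, reason = reason)
  }

  n <- nrow(cohort)
  id <- as.character(cohort$id)
  sex <- parse_sex(cohort$sex)
  num_cols <- intersect(c("age_y", "height_cm", "mass_kg",
                          cohort_replicate_cols(), cohort_reduced_cols(),
                          "r_ohm", "xc_ohm", "uww_db", "adp_db", "bis_tbw_l",
                          grep("^bf_.*_pct$", names(cohort), value = TRUE)),
                        names(cohort))
  parsed <- lapply(cohort[num_cols], as_num)
  bad <- rep(FALSE, n)

  for (i in seq_len(n)) {
    if (is.na(sex[i])) {
      reject(i, id[i], "sex", "unrecognised sex value")
      bad[i] <- TRUE
      next
    }
    for (f in c("age_y", "height_cm", "mass_kg")) {
      v0 <- cohort[[f]][i]
      if (is.na(parsed[[f]][i]) ||
          (!is.na(v0) && !nzchar(trimws(as.character(v0))))) {
        reject(i, id[i], f, sprintf("unparseable numeric value '%s'", v0))
        bad[i] <- TRUE
      }
    }
    if (bad[i]) next
    # unparseable optional numerics reject the row too (silent NA only for
    # genuinely empty cells)
    for (f in setdiff(num_cols, c("age_y", "height_cm", "mass_kg"))) {
      v0 <- trimws(as.character(cohort[[f]][i]))
      if (!is.na(cohort[[f]][i]) && nzchar(v0) && is.na(parsed[[f]][i])) {
        reject(i, id[i], f, sprintf("unparseable numeric value '%s'", v0))
        bad[i] <- TRUE
      }
    }
  }

  out <- tibble::tibble(id = id, sex = sex)
  for (f in num_cols) out[[f]] <- parsed[[f]]
  if ("race_black" %in% names(cohort)) {
    rb <- tolower(trimws(as.character(cohort$race_black)))
    out$race_black <- rb %in% c("true", "t", "1", "yes")
  } else {
    out$race_black <- FALSE
  }

  if (autoconvert_units) {
    m_scale <- !is.na(out$height_cm) & out$height_cm >= 1.2 & out$height_cm <= 2.3
    out$height_cm[m_scale] <- out$height_cm[m_scale] * 100
  }

  has_db <- "uww_db" %in% names(out)
  has_tbw <- "bis_tbw_l" %in% names(out)
  for (i in which(!bad)) {
    if (out$mass_kg[i] <= 0) { reject(i, id[i], "mass_kg", "body mass must be > 0"); bad[i] <- TRUE }
    if (out$height_cm[i] <= 0) { reject(i, id[i], "height_cm", "height must be > 0"); bad[i] <- TRUE }
    if (has_db && !is.na(out$uww_db[i]) &&
        (out$uww_db[i] <= 0.98 || out$uww_db[i] >= 1.12)) {
      reject(i, id[i], "uww_db", "body density outside (0.98, 1.12) kg/L"); bad[i] <- TRUE
    }
    if (has_tbw && !is.na(out$bis_tbw_l[i]) &&
        out$bis_tbw_l[i] >= out$mass_kg[i]) {
      reject(i, id[i], "bis_tbw_l", "total body water must be < body mass"); bad[i] <- TRUE
    }
    for (f in intersect(cohort_replicate_cols(), names(out))) {
      v <- out[[f]][i]
      if (!is.na(v) && (v <= 0 || v >= 100)) {
        reject(i, id[i], f, "skinfold reading outside (0, 100) mm"); bad[i] <- TRUE
      }
    }
  }

  out_age <- !bad & !is.na(out$age_y) & (out$age_y < 14 | out$age_y > 25)
  if (any(out_age)) {
    warning(sum(out_age), " athlete(s) outside the 14-25 y inclusion band: ",
            paste(id[out_age], collapse = ", "), call. = FALSE)
  }

  out <- out[!bad, , drop = FALSE]
  if (reduce) out <- reduce_triplicates(out)
  rejections <- if (length(rej)) dplyr::bind_rows(rej) else
    tibble::tibble(row = integer(), id = character(),
                   field = character(), reason = character())
  attr(out, "rejections") <- rejections
  class(out) <- c("bc_cohort", class(out))
  out
}

#' Rejected rows from a cohort read
#'
#' @param cohort A cohort tibble from [read_cohort()] or [validate_cohort()].
#' @return Tibble with columns `row`, `id`, `field`, `reason`.
#' @export
cohort_rejections <- function(cohort) {
  attr(cohort, "rejections") %||%
    tibble::tibble(row = integer(), id = character(),
                   field = character(), reason = character())
}

#' Average skinfold triplicates
#'
#' Reduces the replicate readings `sf_<site>_1_mm` ... `sf_<site>_3_mm` of each
#' site to their arithmetic mean in `sf_<site>_mm`. Replicates are preserved so
#' test-retest reliability (ICC) remains computable. A site with a single
#' available replicate is used as-is with a warning; a site with no replicates
#' yields `NA` (missing, never zero).
#'
#' @param cohort A cohort tibble carrying replicate columns.
#' @return The cohort with (re)computed `sf_<site>_mm` columns.
#' @export
reduce_triplicates <- function(cohort) {
  singletons <- 0L
  for (site in skinfold_sites()) {
    reps <- intersect(sprintf("sf_%s_%d_mm", site, 1:3), names(cohort))
    if (!length(reps)) next
    m <- as.matrix(cohort[reps])
    k <- rowSums(!is.na(m))
    singletons <- singletons + sum(k == 1L)
    red <- rowMeans(m, na.rm = TRUE)
    red[k == 0L] <- NA_real_
    cohort[[sprintf("sf_%s_mm", site)]] <- red
  }
  if (singletons > 0L) {
    warning(singletons, " site value(s) based on a single replicate reading",
            call. = FALSE)
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' Numeric fields are written at full precision so that
#' `read_cohort(write_cohort(x))` round-trips them exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
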