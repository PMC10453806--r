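#' Minimum wrestling weight
#'
#' Lowest certifiable competition weight at the sport's body-fat floor:
#' current fat-free mass projected to 7% body fat for males and 12% for
#' females,
#' \deqn{MWW_{male} = (1 - BF\%/100) \cdot BM / 0.93, \quad
#'       MWW_{female} = (1 - BF\%/100) \cdot BM / 0.88.}
#' At the floor itself (BF% = 7 male / 12 female) the MWW equals current body
#' mass exactly.
#'
#' @param bm Body mass in kg, > 0.
#' @param bf_percent Body-fat percent, < 100.
#' @param sex `"female"` or `"male"` (recycled).
#' @return Minimum wrestling weight in kg.
#' @examples
#' minimum_wrestling_weight(70, 7, "male")    # 70
#' minimum_wrestling_weight(70, 14, "male")   # 64.73 kg
#' @export
minimum_wrestling_weight <- function(bm, bf_percent, sex) {
  stopifnot(all(bm > 0, na.rm = TRUE), all(bf_percent < 100, na.rm = TRUE))
  divisor <- ifelse(sex == "male", 0.93, 0.88)
  (1 - bf_percent / 100) * bm / divisor
}

#' Weight-class ladders
#'
#' Builds an evenly spaced ladder of weight-class upper limits. Federations
#' commonly space classes about 5.4 kg apart; the base and spacing are
#' configuration, not fixed rules.
#'
#' @param base Upper limit of the lightest class, kg.
#' @param step Class spacing in kg (default 5.4).
#' @param n_classes Number of classes.
#' @return Strictly increasing numeric vector of upper limits.
#' @export
weight_class_table <- function(base, step = 5.4, n_classes = 14) {
  stopifnot(base > 0, step > 0, n_classes >= 1)
  base + step * (seq_len(n_classes) - 1)
}

#' Assign a minimum weight to a weight class
#'
#' Returns the index of the lowest class whose upper limit is at or above the
#' given minimum wrestling weight (upper limits are inclusive: an athlete
#' exactly at a limit makes that class). A weight above the top class gets the
#' sentinel index `length(boundaries) + 1` with a warning. MWW is not rounded
#' before lookup unless `round_to` is given (e.g. `0.1` for federations that
#' round to 0.1 kg).
#'
#' @param mww Minimum wrestling weight(s), kg.
#' @param boundaries Ordered upper limits from [weight_class_table()].
#' @param round_to Optional rounding increment applied before lookup.
#' @return Integer class indices.
#' @export
assign_weight_class <- function(mww, boundaries, round_to = NULL) {
  if (!length(boundaries)) {
    stop("configuration error: empty weight-class table", call. = FALSE)
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("configuration error: boundaries must be strictly increasing",
         call. = FALSE)
  }
  if (!is.null(round_to)) mww <- round(round(mww / round_to) * round_to, 12)
  idx <- rowSums(outer(mww, boundaries, `>`)) + 1L
  over <- !is.na(idx) & idx > length(boundaries)
  if (any(over)) {
    warning(sum(over), " minimum weight(s) above the top class; ",
            "sentinel index ", length(boundaries) + 1L, " assigned",
            call. = FALSE)
  }
  as.integer(idx)
}

#' Weight-class mis-categorization between two methods
#'
#' Counts athletes whose weight class under an alternate method differs from
#' their class under the criterion method, with the directional split (how
#' many land in a lower vs higher class than the criterion).
#'
#' @param criterion,alternate Tibbles with columns `id` and `weight_class`
#'   (integer indices from [assign_weight_class()]), paired by athlete id.
#' @return One-row tibble: `n`, `n_miscategorized`, `fraction`, `n_lower`,
#'   `n_higher`.
#' @export
miscategorization_summary <- function(criterion, alternate) {
  merged <- dplyr::inner_join(
    dplyr::select(criterion, "id", crit_class = "weight_class"),
    dplyr::select(alternate, "id", alt_class = "weight_class"),
    by = "id")
  unpaired <- c(setdiff(criterion$id, alternate$id),
                setdiff(alternate$id, criterion$id))
  if (length(unpaired)) {
    stop("unpaired athlete id(s): ", paste(unpaired, collapse = ", "),
         call. = FALSE)
  }
  diffs <- merged$alt_class - merged$crit_class
  tibble::tibble(
    n = nrow(merged),
    n_miscategorized = sum(diffs != 0L),
    fraction = sum(diffs != 0L) / nrow(merged),
    n_lower = sum(diffs < 0L),
    n_higher = sum(diffs > 0L)
  )
}
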