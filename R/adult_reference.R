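# Adult reference measures: abbreviated-FFQ F&V servings/day and the
# obesogenic dietary index (mean weekly frequency of fast food, French
# fries and soda).

#' Default abbreviated-FFQ item set
#'
#' Seven fruit-and-vegetable items. French fries are captured but
#' excluded from the total; other potatoes are included. The `subgroup`
#' column supports fruit-only and vegetable-only subtotals.
#'
#' @return A tibble with columns `item_id`, `label`, `included`,
#'   `subgroup`.
#' @export
default_ffq_items <- function() {
  tibble::tribble(
    ~item_id,             ~label,                 ~included, ~subgroup,
    "ffq_juice",          "100% fruit juice",     TRUE,      "fruit",
    "ffq_fruit",          "Fruit",                TRUE,      "fruit",
    "ffq_green_salad",    "Green salad",          TRUE,      "vegetable",
    "ffq_fries",          "French fries",         FALSE,     "vegetable",
    "ffq_other_potatoes", "Other potatoes",       TRUE,      "vegetable",
    "ffq_beans",          "Beans",                TRUE,      "vegetable",
    "ffq_other_veg",      "Other vegetables",     TRUE,      "vegetable"
  )
}

#' Total daily F&V servings from the abbreviated FFQ
#'
#' Sums per-item servings/day over the included items (French fries
#' excluded, other potatoes included). Frequency-category capture is
#' assumed to be converted to servings/day upstream; the item table is
#' configuration, not code.
#'
#' @param daily_servings Named numeric vector (names are FFQ item ids) or
#'   a data frame with `item_id` and `daily_servings` columns.
#' @param items FFQ item table, see [default_ffq_items()].
#' @param subgroup Optional `"fruit"` or `"vegetable"` to subtotal.
#' @return Servings/day, or `NA` when no included item was answered.
#' @export
ffq_fv_servings <- function(daily_servings, items = default_ffq_items(),
                            subgroup = NULL) {
  if (is.data.frame(daily_servings)) {
    daily_servings <- stats::setNames(daily_servings$daily_servings,
                                      daily_servings$item_id)
  }
  unknown <- setdiff(names(daily_servings), items$item_id)
  if (length(unknown) > 0) {
    stop("unknown FFQ item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- items$item_id[items$included]
  if (!is.null(subgroup)) {
    keep <- intersect(keep, items$item_id[items$subgroup == subgroup])
  }
  vals <- daily_servings[names(daily_servings) %in% keep]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  if (any(vals < 0)) stop("daily servings must be non-negative",
                          call. = FALSE)
  sum(vals)
}

#' Obesogenic dietary index
#'
#' Mean of the weekly consumption frequencies of fast food, French fries,
#' and soda. All three items are required; any missing item yields `NA`.
#'
#' @param weekly_freq Numeric vector of length 3 (fast food, French
#'   fries, soda) of weekly frequencies, or a named vector containing
#'   `fast_food`, `french_fries`, `soda`.
#' @return Mean weekly frequency, or `NA` if any item is missing.
#' @export
obesogenic_index <- function(weekly_freq) {
  items <- c("fast_food", "french_fries", "soda")
  if (!is.null(names(weekly_freq)) && all(items %in% names(weekly_freq))) {
    weekly_freq <- weekly_freq[items]
  }
  if (length(weekly_freq) != 3) {
    stop("obesogenic index requires exactly 3 weekly frequencies ",
         "(fast food, French fries, soda)", call. = FALSE)
  }
  if (anyNA(weekly_freq)) return(NA_real_)
  if (any(weekly_freq < 0)) {
    stop("weekly frequencies must be non-negative", call. = FALSE)
  }
  mean(weekly_freq)
}

#' Score a long-format adult survey table
#'
#' Expects rows keyed by `subject_id`, `timepoint`, `measure`, `item_id`,
#' `value`, with `measure` either `"ffq"` (value = servings/day) or
#' `"obesogenic"` (value = weekly frequency; item ids `fast_food`,
#' `french_fries`, `soda`).
#'
#' @param adult_survey Long tibble as described.
#' @param items FFQ item table, see [default_ffq_items()].
#' @return A tibble keyed by `subject_id`, `timepoint` with columns
#'   `ffq_fruit`, `ffq_veg`, `ffq_fv`, `obesogenic`.
#' @export
score_adult_survey <- function(adult_survey, items = default_ffq_items()) {
  surv <- tibble::as_tibble(adult_survey)
  bad <- setdiff(unique(surv$measure), c("ffq", "obesogenic"))
  if (length(bad) > 0) {
    stop("unknown measure(s) in adult survey: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  one <- function(g) {
    ffq <- g[g$measure == "ffq", ]
    ob <- g[g$measure == "obesogenic", ]
    sv <- stats::setNames(ffq$value, ffq$item_id)
    ob_v <- stats::setNames(ob$value, ob$item_id)
    tibble::tibble(
      ffq_fruit = if (nrow(ffq) > 0)
        ffq_fv_servings(sv, items, "fruit") else NA_real_,
      ffq_veg = if (nrow(ffq) > 0)
        ffq_fv_servings(sv, items, "vegetable") else NA_real_,
      ffq_fv = if (nrow(ffq) > 0)
        ffq_fv_servings(sv, items) else NA_real_,
      obesogenic = if (nrow(ob) == 3)
        obesogenic_index(ob_v) else NA_real_
    )
  }
  surv |>
    dplyr::group_by(.data$subject_id, .data$timepoint) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}
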