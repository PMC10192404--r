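# Diet scoring: frequency responses -> component servings -> healthy
# eating indices (modified AHEI, healthy foods score, F&V scores, ratio).

#' Default AHEI component scoring standards
#'
#' Cutoffs for the linear 0-10 component scores. Positive components score
#' 0 at zero intake and 10 at the full-score intake; reverse components
#' (SSB/juice, red/processed meat) score 10 at zero intake and 0 at or
#' beyond the zero-score intake. AHEI-2010 gram-based whole-grain cutoffs
#' are replaced by a servings cutoff because a picture-sort records
#' frequencies only. The cutoffs are data, not code: pass a modified
#' tibble to change them.
#'
#' @return A tibble with columns `component`, `direction`,
#'   `zero_score_servings`, `full_score_servings`.
#' @export
default_standards <- function() {
  tibble::tribble(
    ~component,           ~direction, ~zero_score_servings, ~full_score_servings,
    "vegetables",         "positive", 0,                    5,
    "fruit",              "positive", 0,                    4,
    "whole_grains",       "positive", 0,                    1.5,
    "nuts_legumes",       "positive", 0,                    1,
    "ssb_juice",          "reverse",  1,                    0,
    "red_processed_meat", "reverse",  1.5,                  0
  )
}

#' Score one AHEI component from daily servings
#'
#' Linear interpolation between the servings mapped to score 0 and the
#' servings mapped to score 10, clamped to \[0, 10\]. Reverse components
#' have `full_score_servings` (score 10) at zero intake.
#'
#' @param servings Non-negative numeric vector of servings/day.
#' @param standard One row of a standards table (list or one-row data
#'   frame) with `zero_score_servings` and `full_score_servings`.
#' @return Numeric vector of scores in \[0, 10\].
#' @export
score_component <- function(servings, standard) {
  if (any(servings < 0, na.rm = TRUE)) {
    stop("servings must be non-negative", call. = FALSE)
  }
  z <- standard$zero_score_servings
  f <- standard$full_score_servings
  if (isTRUE(all.equal(z, f))) {
    stop("degenerate standard: zero_score_servings equals ",
         "full_score_servings", call. = FALSE)
  }
  pmin(10, pmax(0, 10 * (servings - z) / (f - z)))
}

# Per-group component sums from a joined response table that already has
# servings and registry flags. `g` has columns: servings, ahei_component,
# healthy, is_potato, is_fruit_juice, is_alcohol, is_salad.
sum_components <- function(g, include_salad = TRUE) {
  comp <- g$ahei_component
  veg_in <- comp == "vegetables" & !g$is_potato &
    (include_salad | !g$is_salad)
  fruit_excl <- comp == "fruit" & !g$is_fruit_juice
  tibble::tibble(
    vegetables = sum(g$servings[veg_in]),
    fruit_excl_juice = sum(g$servings[fruit_excl]),
    whole_grains = sum(g$servings[comp == "whole_grains"]),
    nuts_legumes = sum(g$servings[comp == "nuts_legumes"]),
    ssb_juice = sum(g$servings[comp == "ssb_juice"]),
    red_processed_meat = sum(g$servings[comp == "red_processed_meat"]),
    fv_excl_juice = .data$fruit_excl_juice + .data$vegetables,
    healthy_freq = sum(g$servings[g$healthy]),
    total_freq = sum(g$servings[!g$is_alcohol]),
    n_items = nrow(g)
  )
}

#' Component servings for one subject at one timepoint
#'
#' Sums servings/day by AHEI component with the instrument's exclusion
#' rules: potatoes never count toward vegetables, fruit juice counts
#' toward SSB/juice and is excluded from fruit, alcohol is excluded from
#' total food frequency, and healthy frequency sums the four healthy food
#' groups.
#'
#' @param records Response records for a single subject and timepoint.
#' @param registry A validated food registry.
#' @param dialect The `instrument_dialect` for the respondent's role.
#' @param include_salad Should salad items count toward the vegetable
#'   component? Default `TRUE`.
#' @return A one-row tibble of component servings (see [compute_indices()]
#'   for the columns consumed downstream).
#' @export
component_servings <- function(records, registry = default_registry(),
                               dialect = child_dialect(),
                               include_salad = TRUE) {
  rec <- tibble::as_tibble(records)
  if (nrow(rec) == 0) {
    stop("no response records supplied", call. = FALSE)
  }
  if (dplyr::n_distinct(rec$subject_id) > 1 ||
      dplyr::n_distinct(rec$timepoint) > 1) {
    stop("component_servings expects records from one subject at one ",
         "timepoint; use score_diets() for whole tables", call. = FALSE)
  }
  unknown <- setdiff(rec$item_id, registry$item_id)
  if (length(unknown) > 0) {
    stop("item(s) not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g <- dplyr::left_join(rec, registry, by = "item_id")
  g$servings <- frequency_to_servings(g$response, dialect)
  sum_components(g, include_salad = include_salad)
}

#' Healthy eating indices from component servings
#'
#' Computes the six 0-10 component scores and the derived indices:
#' modified AHEI total (0-60, the sum of all six), healthy foods score
#' (0-40, the sum of the four healthy components), fruit and vegetable
#' subscores and their sum (the F&V score, 0-20), and the ratio of
#' healthy-to-total daily servings. The ratio is `NA` when total
#' frequency is zero: a fully non-consuming record is distinguishable
#' from a non-response, never silently scored 0/0 = 0.
#'
#' @param cs A tibble of component servings (one row per subject x
#'   timepoint), as produced by [component_servings()].
#' @param standards A standards table, see [default_standards()].
#' @return `cs` with score and index columns appended.
#' @export
compute_indices <- function(cs, standards = default_standards()) {
  std <- function(component) {
    row <- standards[standards$component == component, ]
    if (nrow(row) != 1) {
      stop("standards table must have exactly one row for component '",
           component, "'", call. = FALSE)
    }
    row
  }
  out <- tibble::as_tibble(cs)
  out$vegetables_score <- score_component(out$vegetables, std("vegetables"))
  out$fruit_score <- score_component(out$fruit_excl_juice, std("fruit"))
  out$whole_grains_score <-
    score_component(out$whole_grains, std("whole_grains"))
  out$nuts_legumes_score <-
    score_component(out$nuts_legumes, std("nuts_legumes"))
  out$ssb_juice_score <- score_component(out$ssb_juice, std("ssb_juice"))
  out$red_processed_meat_score <-
    score_component(out$red_processed_meat, std("red_processed_meat"))
  out$fv_score <- out$fruit_score + out$vegetables_score
  out$healthy_foods_score <- out$fruit_score + out$vegetables_score +
    out$whole_grains_score + out$nuts_legumes_score
  out$modified_ahei_total <- out$healthy_foods_score +
    out$ssb_juice_score + out$red_processed_meat_score
  out$ratio_healthy_total <-
    ifelse(out$total_freq > 0, out$healthy_freq / out$total_freq, NA_real_)
  out
}

#' Score a whole response table into healthy eating indices
#'
#' Validates the response table, converts frequencies to servings with the
#' dialect of each respondent's role, and returns one row of component
#' servings, component scores and indices per subject x timepoint.
#'
#' @inheritParams validate_responses
#' @inheritParams component_servings
#' @param standards A standards table, see [default_standards()].
#' @return A tibble keyed by `subject_id`, `role`, `timepoint`.
#' @export
score_diets <- function(records, registry = default_registry(),
                        dialects = default_dialects(),
                        standards = default_standards(),
                        include_salad = TRUE) {
  rec <- assert_valid_responses(
    validate_responses(records, registry, dialects))
  g <- dplyr::left_join(rec, registry, by = "item_id")
  g$servings <- NA_real_
  for (role in names(dialects)) {
    idx <- g$role == role
    if (any(idx)) {
      g$servings[idx] <-
        frequency_to_servings(g$response[idx], dialects[[role]])
    }
  }
  cs <- g |>
    dplyr::group_by(.data$subject_id, .data$role, .data$timepoint) |>
    dplyr::group_modify(~ sum_components(.x, include_salad = include_salad)) |>
    dplyr::ungroup()
  compute_indices(cs, standards)
}
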