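# Psychosocial scale scoring: 4-point Likert scales for tendency to
# choose F&V and self-efficacy for F&V, with Cronbach alpha internal
# consistency and a single-item removal rule.

#' Default psychosocial scale definitions
#'
#' Long-format scale membership for the child instrument: a 6-item
#' tendency-to-choose measure (3 fruit, 3 vegetable items) and an 8-item
#' self-efficacy measure (4 fruit, 4 vegetable items) whose eating-only
#' subset forms the 5-item self-efficacy score used as the child
#' reference measure. Items are shared across derived scales (the 5-item
#' scale is a subset of the 8-item one). All scales use a 4-point Likert
#' response with no neutral midpoint.
#'
#' @return A tibble with columns `scale_id`, `item_id`, `subscale`
#'   (`"fruit"` or `"vegetable"`).
#' @export
default_scales <- function() {
  tc_f <- c("tc_fruit_snack", "tc_fruit_meal", "tc_fruit_treat")
  tc_v <- c("tc_veg_lunch", "tc_veg_dinner", "tc_veg_snack")
  se_f_eat <- c("se_fruit_lunch", "se_fruit_dessert", "se_fruit_cereal")
  se_f_all <- c(se_f_eat, "se_fruit_bring")
  se_v_eat <- c("se_veg_lunch", "se_veg_dinner")
  se_v_all <- c(se_v_eat, "se_veg_bring", "se_veg_cook")
  mk <- function(scale_id, items, subscale) {
    tibble::tibble(scale_id = scale_id, item_id = items, subscale = subscale)
  }
  dplyr::bind_rows(
    mk("tendency_fruit", tc_f, "fruit"),
    mk("tendency_veg", tc_v, "vegetable"),
    mk("tendency_fv", c(tc_f, tc_v), rep(c("fruit", "vegetable"), each = 3)),
    mk("se_fruit_eat", se_f_eat, "fruit"),
    mk("se_fruit_all", se_f_all, "fruit"),
    mk("se_veg_eat", se_v_eat, "vegetable"),
    mk("se_veg_all", se_v_all, "vegetable"),
    mk("se_fv_5", c(se_f_eat, se_v_eat),
       c(rep("fruit", 3), rep("vegetable", 2))),
    mk("se_fv_8", c(se_f_all, se_v_all),
       c(rep("fruit", 4), rep("vegetable", 4)))
  )
}

#' Item families behind the default scales
#'
#' Distinct Likert items grouped by instrument family; derived scales are
#' subsets of a family's items.
#'
#' @return A tibble with columns `family`, `item_id`.
#' @export
default_scale_items <- function() {
  sc <- default_scales()
  tibble::tibble(
    item_id = unique(sc$item_id),
    family = ifelse(startsWith(unique(sc$item_id), "tc_"),
                    "tendency", "self_efficacy")
  )[, c("family", "item_id")]
}

#' Rescale a score to the unit interval
#'
#' Affine rescaling by subtracting the lowest possible value and dividing
#' by the possible range, so instruments with different theoretical
#' ranges can be compared by coefficient of variation.
#'
#' @param x Numeric vector.
#' @param min,max Theoretical minimum and maximum of the scale.
#' @return Numeric vector in \[0, 1\].
#' @export
rescale_score <- function(x, min = 1, max = 4) {
  if (max <= min) stop("max must exceed min", call. = FALSE)
  (x - min) / (max - min)
}

#' Score one psychosocial scale for one respondent
#'
#' Arithmetic mean of the answered items (optionally restricted to a
#' subscale), with the rescaled value on \[0, 1\]. Zero answered items
#' gives an `NA` score with `n_items_answered = 0` rather than an error.
#'
#' @param responses Named numeric vector (names are item ids) or a data
#'   frame with `item_id` and `response` columns.
#' @param scale A scale definition: the rows of [default_scales()] for
#'   one `scale_id`.
#' @param subscale Optional subscale tag (`"fruit"` or `"vegetable"`) to
#'   filter items before averaging.
#' @param likert_min,likert_max Scale endpoints (default 1 and 4).
#' @return A one-row tibble: `mean_score`, `rescaled`, `n_items_answered`.
#' @export
scale_mean <- function(responses, scale, subscale = NULL,
                       likert_min = 1, likert_max = 4) {
  if (is.data.frame(responses)) {
    responses <- stats::setNames(responses$response, responses$item_id)
  }
  items <- scale$item_id
  if (!is.null(subscale)) {
    items <- scale$item_id[scale$subscale == subscale]
  }
  vals <- responses[names(responses) %in% items]
  vals <- vals[!is.na(vals)]
  if (length(vals) > 0 &&
      (min(vals) < likert_min || max(vals) > likert_max)) {
    stop("Likert responses outside [", likert_min, ", ", likert_max, "]",
         call. = FALSE)
  }
  m <- if (length(vals) == 0) NA_real_ else mean(vals)
  tibble::tibble(
    mean_score = m,
    rescaled = rescale_score(m, likert_min, likert_max),
    n_items_answered = length(vals)
  )
}

#' Score all psychosocial scales for a cohort
#'
#' @param likert Long tibble with columns `subject_id`, `timepoint`,
#'   `item_id`, `response` (Likert integers).
#' @param scales Scale definitions, see [default_scales()].
#' @inheritParams scale_mean
#' @return A tibble keyed by `subject_id`, `timepoint`, `scale_id` with
#'   `mean_score`, `rescaled`, `n_items_answered`.
#' @export
score_scales <- function(likert, scales = default_scales(),
                         likert_min = 1, likert_max = 4) {
  lk <- tibble::as_tibble(likert)
  dplyr::inner_join(lk, scales, by = "item_id",
                    relationship = "many-to-many") |>
    dplyr::group_by(.data$subject_id, .data$timepoint, .data$scale_id) |>
    dplyr::summarise(
      mean_score = mean(.data$response[!is.na(.data$response)]),
      n_items_answered = sum(!is.na(.data$response)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rescaled = rescale_score(.data$mean_score, likert_min, likert_max)
    ) |>
    dplyr::select("subject_id", "timepoint", "scale_id", "mean_score",
                  "rescaled", "n_items_answered")
}

#' Cronbach's alpha
#'
#' Internal consistency of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`,
#' with sample variances (n-1 denominator) over complete cases.
#'
#' @param item_matrix Numeric matrix or data frame, subjects in rows,
#'   items in columns.
#' @return Alpha (can be negative for incoherent scales).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop("alpha requires at least 2 items", call. = FALSE)
  if (nrow(m) < 3) stop("alpha requires at least 3 subjects", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("degenerate scale: total score has zero variance",
                           call. = FALSE)
  item_var <- apply(m, 2, stats::var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Alpha if each item were deleted
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector: alpha of the scale with that item removed.
#' @export
alpha_if_deleted <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 3) {
    stop("alpha-if-deleted requires at least 3 items ",
         "(deleting from a 2-item scale leaves no scale)", call. = FALSE)
  }
  out <- vapply(seq_len(ncol(m)),
                function(j) cronbach_alpha(m[, -j, drop = FALSE]),
                numeric(1))
  stats::setNames(out, colnames(m))
}

#' Single-item removal decision from alpha values
#'
#' An item is removed when deleting it improves internal consistency by
#' more than `threshold` in relative terms:
#' `(alpha_after - alpha) / |alpha| > threshold`. The rule is relative,
#' not absolute-points: an alpha of 0.31 improving to 0.67 (+116%)
#' removes, 0.60 to 0.65 (+8%) does not. At most one item is ever
#' removed. A non-positive baseline alpha still yields a decision (any
#' positive improvement over a non-positive baseline qualifies) but is
#' flagged.
#'
#' @param alpha Baseline alpha of the full scale.
#' @param loo_alphas Named vector of alpha-if-deleted values.
#' @param threshold Relative improvement required (default 0.30).
#' @return A list: `remove` (logical), `removed_item`, `alpha_after`,
#'   `relative_improvement`, `baseline_nonpositive`.
#' @export
removal_decision <- function(alpha, loo_alphas, threshold = 0.30) {
  best <- which.max(loo_alphas) # ties: first item in scale order
  alpha_after <- loo_alphas[[best]]
  nonpos <- alpha <= 0
  rel <- if (nonpos) {
    if (alpha_after > 0) Inf else NA_real_
  } else {
    (alpha_after - alpha) / alpha
  }
  remove <- isTRUE(rel > threshold)
  list(
    remove = remove,
    removed_item = if (remove) names(loo_alphas)[best] else NA_character_,
    alpha_after = if (remove) alpha_after else NA_real_,
    best_item = names(loo_alphas)[best],
    best_alpha = alpha_after,
    relative_improvement = rel,
    baseline_nonpositive = nonpos
  )
}

#' Internal consistency report with single-item removal
#'
#' Computes Cronbach's alpha, alpha-if-deleted for every item, and
#' applies the removal rule of [removal_decision()]. Two-item scales
#' cannot lose an item (the remainder would not be a scale); they report
#' alpha with no removal candidates.
#'
#' @inheritParams cronbach_alpha
#' @param threshold Relative improvement required for removal.
#' @return A list of class `alpha_report`: `alpha`, `loo_alphas`,
#'   `removed_item`, `alpha_after`, `decision` (the full
#'   [removal_decision()] output), `k`, `n`.
#' @export
alpha_item_removal <- function(item_matrix, threshold = 0.30) {
  m <- as.matrix(item_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  alpha <- cronbach_alpha(m)
  if (ncol(m) == 2) {
    res <- list(alpha = alpha, loo_alphas = NULL,
                removed_item = NA_character_, alpha_after = NA_real_,
                decision = NULL, k = 2L, n = nrow(m))
    class(res) <- "alpha_report"
    return(res)
  }
  loo <- alpha_if_deleted(m)
  dec <- removal_decision(alpha, loo, threshold)
  res <- list(alpha = alpha, loo_alphas = loo,
              removed_item = dec$removed_item,
              alpha_after = dec$alpha_after,
              decision = dec, k = ncol(m), n = nrow(m))
  class(res) <- "alpha_report"
  res
}

#' @export
print.alpha_report <- function(x, ...) {
  cat(sprintf("Cronbach alpha: %.3f (%d items, n = %d)\n",
              x$alpha, x$k, x$n))
  if (!is.null(x$loo_alphas)) {
    if (!is.na(x$removed_item)) {
      cat(sprintf("Removed '%s': alpha improves to %.3f\n",
                  x$removed_item, x$alpha_after))
    } else {
      cat(sprintf("No item removed (best alpha-if-deleted %.3f)\n",
                  max(x$loo_alphas)))
    }
  }
  invisible(x)
}

#' Coefficient of variation
#'
#' SD divided by mean; intended for scores rescaled to \[0, 1\] so that
#' instruments with different theoretical ranges are comparable. Note the
#' CoV is not invariant to the rescaling shift, which is exactly why a
#' common scale is required first. A zero mean yields `NA`.
#'
#' @param values Numeric vector (NAs dropped).
#' @return SD/mean, or `NA` when the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  v <- values[!is.na(values)]
  m <- mean(v)
  if (m == 0) return(NA_real_)
  stats::sd(v) / m
}
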