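# End-to-end validation-study pipeline: score diets and scales, run
# internal consistency with item removal, convergent validity with the
# retention filter, and Bland-Altman reliability on the retained
# indices; emit the four report tables plus completion rates.

# The picture-sort indices carried through validity and reliability.
index_columns <- c(
  fruits_only = "fruit_excl_juice",
  vegetables_only = "vegetables",
  fv_excl_juice = "fv_excl_juice",
  fv_score = "fv_score",
  healthy_foods_score = "healthy_foods_score",
  modified_ahei_total = "modified_ahei_total",
  ratio_healthy_total = "ratio_healthy_total"
)

#' Follow-up completion rates by role
#'
#' The feasibility yardstick: the proportion of baseline respondents who
#' also completed follow-up, per role, as a percentage.
#'
#' @param responses Long response tibble with `subject_id`, `role`,
#'   `timepoint`.
#' @return A tibble: `role`, `n_baseline`, `n_followup`, `completion_pct`.
#' @export
completion_rates <- function(responses) {
  rec <- tibble::as_tibble(responses)
  rec |>
    dplyr::distinct(.data$subject_id, .data$role, .data$timepoint) |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(
      n_baseline = dplyr::n_distinct(
        .data$subject_id[.data$timepoint == "baseline"]),
      n_followup = dplyr::n_distinct(
        .data$subject_id[.data$timepoint == "followup" &
                           .data$subject_id %in%
                             .data$subject_id[.data$timepoint == "baseline"]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      completion_pct = 100 * .data$n_followup / .data$n_baseline)
}

wide_indices <- function(index_scores, role, timepoint) {
  sub <- index_scores[index_scores$role == role &
                        index_scores$timepoint == timepoint, ]
  out <- tibble::tibble(subject_id = sub$subject_id)
  for (nm in names(index_columns)) out[[nm]] <- sub[[index_columns[[nm]]]]
  out
}

wide_scales <- function(scale_scores, timepoint, which_scales = NULL) {
  sub <- scale_scores[scale_scores$timepoint == timepoint, ]
  if (!is.null(which_scales)) {
    sub <- sub[sub$scale_id %in% which_scales, ]
  }
  tidyr::pivot_wider(sub[, c("subject_id", "scale_id", "mean_score")],
                     names_from = "scale_id", values_from = "mean_score")
}

mean_sd_rows <- function(tbl, cols, cohort, timepoint) {
  rows <- lapply(cols, function(cl) {
    v <- tbl[[cl]]
    tibble::tibble(cohort = cohort, timepoint = timepoint, measure = cl,
                   n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
                   sd = stats::sd(v, na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}

#' Run the full validation-study pipeline
#'
#' Executes the analysis stages in study order on a cohort (real data
#' loaded through the package's readers, or a [generate_cohort()]
#' output):
#' 1. score picture-sort diets at both timepoints;
#' 2. score the child psychosocial scales and evaluate internal
#'    consistency with the single-item removal rule;
#' 3. re-score the revised scales and compute the baseline
#'    convergent-validity correlation matrix (children: indices vs
#'    psychosocial scores; adults: indices vs FFQ F&V and obesogenic
#'    index);
#' 4. apply the retention filter (children: 5-item self-efficacy for
#'    eating F&V, positive; adults: FFQ F&V positive or obesogenic
#'    negative);
#' 5. Bland-Altman test-retest analysis of every retained index;
#' 6. summarise descriptives and follow-up completion.
#'
#' The report is a pure function of its inputs: rerunning on the same
#' cohort reproduces it exactly.
#'
#' @param cohort A list with elements `responses`, `likert`,
#'   `adult_survey`, and optionally `registry`, `scales`, `dialects`,
#'   `ffq_items` (defaults used when absent), e.g. a `synthetic_cohort`.
#' @param p_retention Retention p-value threshold (default 0.1).
#' @param alpha_removal_threshold Relative alpha improvement required to
#'   drop an item (default 0.30).
#' @param child_reference Scale id of the child reference measure.
#' @param diff_sign Bland-Altman difference convention, see
#'   [bland_altman()].
#' @param include_salad Should salad count toward the vegetable
#'   component?
#' @param standards Component scoring standards.
#' @return An object of class `validation_report`: a list of tibbles
#'   `descriptives`, `internal_consistency`, `correlations`, `retention`,
#'   `reliability`, `completion`, plus `indices`, `scale_scores`,
#'   `adult_scores`, `retained` (character), and `provenance`.
#' @export
run_validation_study <- function(cohort,
                                 p_retention = 0.1,
                                 alpha_removal_threshold = 0.30,
                                 child_reference = "se_fv_5",
                                 diff_sign = "followup-baseline",
                                 include_salad = TRUE,
                                 standards = default_standards()) {
  if (p_retention <= 0 || p_retention >= 1) {
    stop("p_retention must lie in (0, 1)", call. = FALSE)
  }
  if (alpha_removal_threshold <= 0 || alpha_removal_threshold >= 1) {
    stop("alpha_removal_threshold must lie in (0, 1)", call. = FALSE)
  }
  registry <- cohort$registry %||% default_registry()
  scales <- cohort$scales %||% default_scales()
  dialects <- cohort$dialects %||% default_dialects()
  ffq_items <- cohort$ffq_items %||% default_ffq_items()

  # stage 1: diet indices ------------------------------------------------
  indices <- score_diets(cohort$responses, registry, dialects, standards,
                         include_salad = include_salad)
  have_children <- any(indices$role == "child")
  have_adults <- any(indices$role == "adult")

  # stage 2: internal consistency on baseline child Likert data ----------
  internal <- tibble::tibble()
  revised_scales <- scales
  if (nrow(cohort$likert) > 0) {
    base_lk <- cohort$likert[cohort$likert$timepoint == "baseline", ]
    item_mat <- function(ids) {
      wide <- tidyr::pivot_wider(
        base_lk[base_lk$item_id %in% ids,
                c("subject_id", "item_id", "response")],
        names_from = "item_id", values_from = "response")
      as.matrix(wide[, ids[ids %in% names(wide)], drop = FALSE])
    }
    rows <- list()
    for (sid in unique(scales$scale_id)) {
      ids <- scales$item_id[scales$scale_id == sid]
      m <- item_mat(ids)
      rep_row <- tryCatch({
        rep <- alpha_item_removal(m, alpha_removal_threshold)
        tibble::tibble(
          scale_id = sid, n_items = rep$k, n = rep$n, alpha = rep$alpha,
          alpha_if_item_deleted =
            if (is.null(rep$loo_alphas)) NA_real_ else max(rep$loo_alphas),
          removed_item = rep$removed_item,
          alpha_after = rep$alpha_after)
      }, error = function(e) {
        tibble::tibble(scale_id = sid, n_items = ncol(m),
                       n = nrow(m), alpha = NA_real_,
                       alpha_if_item_deleted = NA_real_,
                       removed_item = NA_character_,
                       alpha_after = NA_real_)
      })
      rows[[sid]] <- rep_row
      if (!is.na(rep_row$removed_item)) {
        revised_scales <- revised_scales[
          !(revised_scales$scale_id == sid &
              revised_scales$item_id == rep_row$removed_item), ]
      }
    }
    internal <- dplyr::bind_rows(rows)
  }

  # stage 3: scale scores on revised scales + adult reference scores -----
  scale_scores <- if (nrow(cohort$likert) > 0) {
    score_scales(cohort$likert, revised_scales)
  } else {
    tibble::tibble(subject_id = character(), timepoint = character(),
                   scale_id = character(), mean_score = numeric(),
                   rescaled = numeric(), n_items_answered = integer())
  }
  adult_scores <- if (nrow(cohort$adult_survey) > 0) {
    score_adult_survey(cohort$adult_survey, ffq_items)
  } else {
    tibble::tibble(subject_id = character(), timepoint = character(),
                   ffq_fruit = numeric(), ffq_veg = numeric(),
                   ffq_fv = numeric(), obesogenic = numeric())
  }

  # stage 4: convergent validity at baseline -----------------------------
  correlations <- tibble::tibble()
  retention <- tibble::tibble()
  if (have_children && nrow(scale_scores) > 0) {
    child_ref_tbl <- wide_scales(scale_scores, "baseline")
    child_cor <- convergent_validity_matrix(
      wide_indices(indices, "child", "baseline"), child_ref_tbl)
    child_cor$cohort <- "children"
    correlations <- dplyr::bind_rows(correlations, child_cor)
    child_ret <- retention_filter(
      child_cor,
      tibble::tibble(reference = child_reference, expected_sign = "+"),
      p_retention)
    child_ret$cohort <- "children"
    retention <- dplyr::bind_rows(retention, child_ret)
  }
  if (have_adults && nrow(adult_scores) > 0) {
    adult_ref_tbl <- adult_scores[adult_scores$timepoint == "baseline",
                                  c("subject_id", "ffq_fruit", "ffq_veg",
                                    "ffq_fv", "obesogenic")]
    adult_cor <- convergent_validity_matrix(
      wide_indices(indices, "adult", "baseline"), adult_ref_tbl)
    adult_cor$cohort <- "adults"
    correlations <- dplyr::bind_rows(correlations, adult_cor)
    adult_ret <- retention_filter(
      adult_cor,
      tibble::tibble(reference = c("ffq_fv", "obesogenic"),
                     expected_sign = c("+", "-")),
      p_retention)
    adult_ret$cohort <- "adults"
    retention <- dplyr::bind_rows(retention, adult_ret)
  }
  retained <- if (nrow(retention) > 0) {
    retention |>
      dplyr::filter(.data$retained) |>
      dplyr::distinct(.data$cohort, .data$index)
  } else {
    tibble::tibble(cohort = character(), index = character())
  }

  # stage 5: Bland-Altman reliability of retained indices ----------------
  rel_rows <- list()
  for (i in seq_len(nrow(retained))) {
    coh <- retained$cohort[i]
    idx <- retained$index[i]
    role <- if (coh == "children") "child" else "adult"
    base <- wide_indices(indices, role, "baseline")
    fup <- wide_indices(indices, role, "followup")
    if (nrow(fup) < 3) next
    ba <- tryCatch(
      bland_altman(stats::setNames(base[[idx]], base$subject_id),
                   stats::setNames(fup[[idx]], fup$subject_id),
                   diff_sign = diff_sign),
      error = function(e) NULL)
    if (is.null(ba)) next
    rel_rows[[paste(coh, idx)]] <- tibble::tibble(
      cohort = coh, index = idx, n = ba$n,
      baseline_mean = mean(ba$pairs$baseline),
      baseline_sd = stats::sd(ba$pairs$baseline),
      followup_mean = mean(ba$pairs$followup),
      followup_sd = stats::sd(ba$pairs$followup),
      mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      repeatability = ba$repeatability,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      pct_within = ba$pct_within,
      reliability_coefficient = ba$reliability_coefficient)
  }
  reliability <- dplyr::bind_rows(rel_rows)

  # stage 6: descriptives and completion ---------------------------------
  descr <- list()
  if (have_children) {
    descr$child_idx <- mean_sd_rows(wide_indices(indices, "child",
                                                 "baseline"),
                                    names(index_columns), "children",
                                    "baseline")
  }
  if (have_adults) {
    descr$adult_idx <- mean_sd_rows(wide_indices(indices, "adult",
                                                 "baseline"),
                                    names(index_columns), "adults",
                                    "baseline")
    if (nrow(adult_scores) > 0) {
      descr$adult_ref <- mean_sd_rows(
        adult_scores[adult_scores$timepoint == "baseline", ],
        c("ffq_fruit", "ffq_veg", "ffq_fv", "obesogenic"),
        "adults", "baseline")
    }
  }
  if (nrow(scale_scores) > 0) {
    descr$scales <- scale_scores |>
      dplyr::filter(.data$timepoint == "baseline") |>
      dplyr::group_by(.data$scale_id) |>
      dplyr::summarise(n = dplyr::n(),
                       mean = mean(.data$mean_score),
                       sd = stats::sd(.data$mean_score),
                       .groups = "drop") |>
      dplyr::mutate(cohort = "children", timepoint = "baseline") |>
      dplyr::rename(measure = "scale_id") |>
      dplyr::select("cohort", "timepoint", "measure", "n", "mean", "sd")
  }
  descriptives <- dplyr::bind_rows(descr)
  completion <- completion_rates(cohort$responses)

  res <- list(
    descriptives = descriptives,
    internal_consistency = internal,
    correlations = correlations,
    retention = retention,
    reliability = reliability,
    completion = completion,
    indices = indices,
    scale_scores = scale_scores,
    adult_scores = adult_scores,
    retained = retained,
    provenance = list(
      package_version = as.character(utils::packageVersion("picturesort")),
      p_retention = p_retention,
      alpha_removal_threshold = alpha_removal_threshold,
      child_reference = child_reference,
      diff_sign = diff_sign,
      include_salad = include_salad,
      input_hash = rlang::hash(list(cohort$responses, cohort$likert,
                                    cohort$adult_survey))
    )
  )
  class(res) <- "validation_report"
  res
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Picture-sort validation study report\n")
  for (i in seq_len(nrow(x$completion))) {
    cat(sprintf("  %s: %d baseline, %d follow-up (%.0f%% completion)\n",
                x$completion$role[i], x$completion$n_baseline[i],
                x$completion$n_followup[i], x$completion$completion_pct[i]))
  }
  if (nrow(x$retained) > 0) {
    cat("  retained indices:\n")
    for (coh in unique(x$retained$cohort)) {
      cat(sprintf("    %s: %s\n", coh,
                  paste(x$retained$index[x$retained$cohort == coh],
                        collapse = ", ")))
    }
  } else {
    cat("  no indices retained\n")
  }
  cat(sprintf("  tables: %d descriptive rows, %d alpha rows, %d correlations, %d reliability rows\n",
              nrow(x$descriptives), nrow(x$internal_consistency),
              nrow(x$correlations), nrow(x$reliability)))
  invisible(x)
}

round_df <- function(df, digits_map) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      d <- digits_map[["default"]]
      if (nm %in% names(digits_map)) d <- digits_map[[nm]]
      df[[nm]] <- round(df[[nm]], d)
    }
  }
  df
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, body)
}

report_tables <- c("descriptives", "internal_consistency", "correlations",
                   "retention", "reliability", "completion")

#' Render a validation report to files
#'
#' `csv` writes one file per table, lossless (full precision). `json`
#' writes a single `report.json`, lossless. `markdown` writes
#' `report.md` with display rounding: one decimal for scores and
#' descriptives, two for correlations, ratios and alphas.
#'
#' @param report A `validation_report`.
#' @param fmt One of `"csv"`, `"json"`, `"markdown"`.
#' @param dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, fmt = c("csv", "json", "markdown"), dir) {
  stopifnot(inherits(report, "validation_report"))
  fmt <- match.arg(fmt)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (fmt == "csv") {
    for (nm in report_tables) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], path, row.names = FALSE)
      written <- c(written, path)
    }
  } else if (fmt == "json") {
    path <- file.path(dir, "report.json")
    payload <- c(report[report_tables],
                 list(retained = report$retained,
                      provenance = report$provenance))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- path
  } else {
    path <- file.path(dir, "report.md")
    lines <- c("# Picture-sort validation study", "")
    sections <- list(
      descriptives = list(
        title = "Baseline descriptives",
        digits = list(default = 1, mean = 1, sd = 1)),
      internal_consistency = list(
        title = "Internal consistency (Cronbach alpha)",
        digits = list(default = 2)),
      correlations = list(
        title = "Convergent validity (Pearson r)",
        digits = list(default = 2, p = 3)),
      retention = list(
        title = "Retention decisions",
        digits = list(default = 2, p = 3)),
      reliability = list(
        title = "Test-retest reliability (Bland-Altman)",
        digits = list(default = 1, reliability_coefficient = 2)),
      completion = list(
        title = "Follow-up completion",
        digits = list(default = 0))
    )
    for (nm in names(sections)) {
      tbl <- report[[nm]]
      lines <- c(lines, paste("##", sections[[nm]]$title), "")
      if (nrow(tbl) > 0) {
        lines <- c(lines, md_table(round_df(tbl, sections[[nm]]$digits)), "")
      } else {
        lines <- c(lines, "(empty)", "")
      }
    }
    lines <- c(lines,
               "The reliability coefficient is a within-person variance",
               "interpretation: 1 - var(diff)/2 / var(pooled values).")
    writeLines(lines, path)
    written <- path
  }
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
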