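# Convergent validity: Pearson correlations between picture-sort indices
# and reference measures, significance flags, and the retention filter.

#' Pearson correlation with a two-sided p-value
#'
#' Standard Pearson r over complete pairs, with the p-value from the t
#' transform `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom,
#' two-sided (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @param var_x,var_y Names to report for the pair.
#' @return A one-row tibble: `var_x`, `var_y`, `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y, var_x = "x", var_y = "y") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: zero variance in '",
         if (stats::sd(x) == 0) var_x else var_y, "'", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(var_x = var_x, var_y = var_y,
                 r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Significance flag at the conventional reporting thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"p<0.001"`, `"p<=0.01"`, `"p<0.05"`,
#'   `"p<0.1"`, or `""`.
#' @export
significance_flag <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "p<0.001",
    p <= 0.01 ~ "p<=0.01",
    p < 0.05 ~ "p<0.05",
    p < 0.1 ~ "p<0.1",
    TRUE ~ ""
  )
}

#' Convergent-validity correlation matrix in long format
#'
#' Correlates every numeric index column against every numeric reference
#' column, pairwise complete, joined on subject id. Pairs with fewer than
#' 3 complete observations or zero variance are reported with `NA`
#' correlation rather than dropped silently.
#'
#' @param index_table Wide tibble: `subject_id` plus index columns.
#' @param reference_table Wide tibble: `subject_id` plus reference
#'   columns.
#' @param by Join key, default `"subject_id"`.
#' @return A long tibble: `var_x` (index), `var_y` (reference), `r`, `p`,
#'   `n`, `flag`.
#' @export
convergent_validity_matrix <- function(index_table, reference_table,
                                       by = "subject_id") {
  idx <- tibble::as_tibble(index_table)
  ref <- tibble::as_tibble(reference_table)
  joined <- dplyr::inner_join(idx, ref, by = by,
                              suffix = c("_index", "_reference"))
  if (nrow(joined) == 0) {
    stop("no overlapping subjects between index and reference tables",
         call. = FALSE)
  }
  num <- function(tbl) setdiff(names(tbl)[vapply(tbl, is.numeric,
                                                 logical(1))], by)
  xcols <- num(idx)
  ycols <- num(ref)
  resolve <- function(col, suffix) {
    if (col %in% names(joined)) col else paste0(col, suffix)
  }
  out <- list()
  for (xc in xcols) {
    for (yc in ycols) {
      xv <- joined[[resolve(xc, "_index")]]
      yv <- joined[[resolve(yc, "_reference")]]
      row <- tryCatch(
        pearson_with_p(xv, yv, var_x = xc, var_y = yc),
        error = function(e) {
          tibble::tibble(var_x = xc, var_y = yc, r = NA_real_,
                         p = NA_real_, n = sum(stats::complete.cases(xv, yv)))
        }
      )
      out[[paste(xc, yc, sep = "\r")]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  res$flag <- ifelse(is.na(res$p), "", significance_flag(res$p))
  res
}

#' Retention filter for picture-sort indices
#'
#' An index is retained when it is significantly correlated, in the
#' expected direction, with at least one reference measure: `p <=
#' p_threshold` and `sign(r)` matching `expected_sign`. Correlations with
#' `p > p_threshold` are not retained (the boundary case `p` exactly at
#' the threshold passes).
#'
#' @param results Long correlation results from
#'   [convergent_validity_matrix()].
#' @param reference_spec Tibble with columns `reference` (must appear in
#'   `results$var_y`) and `expected_sign` (`"+"` or `"-"`).
#' @param p_threshold Retention p-value threshold (default 0.1).
#' @return A tibble with one row per index x reference: `index`,
#'   `reference`, `r`, `p`, `expected_sign`, `passes`, plus the per-index
#'   `retained` flag (TRUE when any reference passes) and a `reason`.
#' @export
retention_filter <- function(results, reference_spec, p_threshold = 0.1) {
  spec <- tibble::as_tibble(reference_spec)
  stopifnot(all(c("reference", "expected_sign") %in% names(spec)))
  if (!all(spec$expected_sign %in% c("+", "-"))) {
    stop("expected_sign must be '+' or '-'", call. = FALSE)
  }
  unknown <- setdiff(spec$reference, unique(results$var_y))
  if (length(unknown) > 0) {
    stop("reference(s) not present in correlation results: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dec <- results |>
    dplyr::inner_join(spec, by = c("var_y" = "reference")) |>
    dplyr::mutate(
      sign_ok = ifelse(.data$expected_sign == "+", .data$r > 0, .data$r < 0),
      passes = !is.na(.data$p) & .data$p <= p_threshold & .data$sign_ok,
      reason = dplyr::case_when(
        is.na(.data$p) ~ "correlation not estimable",
        .data$p > p_threshold ~ sprintf("p = %.3f > %.2f", .data$p,
                                        p_threshold),
        !.data$sign_ok ~ sprintf("sign of r (%+.2f) opposite to expected %s",
                                 .data$r, .data$expected_sign),
        TRUE ~ sprintf("p = %.3f <= %.2f, expected sign", .data$p,
                       p_threshold)
      )
    ) |>
    dplyr::rename(index = "var_x", reference = "var_y") |>
    dplyr::select("index", "reference", "r", "p", "n", "expected_sign",
                  "passes", "reason")
  dec |>
    dplyr::group_by(.data$index) |>
    dplyr::mutate(retained = any(.data$passes)) |>
    dplyr::ungroup()
}
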