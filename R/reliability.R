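# Test-retest reliability: Bland-Altman limits of agreement,
# repeatability coefficient, and a within-person-variance reliability
# coefficient.

#' Bland-Altman agreement analysis of two timepoints
#'
#' Pairs baseline and follow-up values by subject (by name when both
#' vectors are named, by position otherwise), computes per-subject
#' differences and means, the mean difference, the SD of differences
#' (n-1 denominator), the limits of agreement `mean_diff +/- 1.96 *
#' sd_diff`, the repeatability coefficient `1.96 * sd_diff`, the
#' percentage of differences inside the closed interval of the limits,
#' and the reliability coefficient of [reliability_coefficient()].
#'
#' The difference sign convention defaults to follow-up minus baseline;
#' set `diff_sign = "baseline-followup"` for the opposite convention.
#' Subjects missing either timepoint are excluded and counted.
#'
#' @param baseline,followup Numeric vectors of a healthy eating index at
#'   the two timepoints, optionally named by subject id.
#' @param diff_sign `"followup-baseline"` (default) or
#'   `"baseline-followup"`.
#' @param coverage_z Multiplier of `sd_diff` for the limits (default
#'   1.96, the 95% normal coverage).
#' @return An object of class `bland_altman`: a list with `n`,
#'   `n_excluded`, `mean_diff`, `sd_diff`, `repeatability`, `loa_lower`,
#'   `loa_upper`, `pct_within`, `reliability_coefficient`, `diff_sign`,
#'   and the per-subject `pairs` tibble.
#' @export
bland_altman <- function(baseline, followup,
                         diff_sign = c("followup-baseline",
                                       "baseline-followup"),
                         coverage_z = 1.96) {
  diff_sign <- match.arg(diff_sign)
  if (!is.null(names(baseline)) && !is.null(names(followup))) {
    ids <- intersect(names(baseline), names(followup))
    n_excluded <- (length(baseline) - length(ids)) +
      (length(followup) - length(ids))
    baseline <- baseline[ids]
    followup <- followup[ids]
  } else {
    if (length(baseline) != length(followup)) {
      stop("unnamed baseline and followup vectors must have equal length",
           call. = FALSE)
    }
    ids <- if (!is.null(names(baseline))) names(baseline)
           else as.character(seq_along(baseline))
    n_excluded <- 0L
  }
  ok <- stats::complete.cases(baseline, followup)
  n_excluded <- n_excluded + sum(!ok)
  baseline <- baseline[ok]
  followup <- followup[ok]
  ids <- ids[ok]
  n <- length(baseline)
  if (n < 3) {
    stop("Bland-Altman analysis requires at least 3 complete pairs ",
         "(have ", n, ")", call. = FALSE)
  }
  d <- if (diff_sign == "followup-baseline") followup - baseline
       else baseline - followup
  m <- (baseline + followup) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  loa_lower <- mean_diff - coverage_z * sd_diff
  loa_upper <- mean_diff + coverage_z * sd_diff
  res <- list(
    n = n,
    n_excluded = as.integer(n_excluded),
    mean_diff = mean_diff,
    sd_diff = sd_diff,
    repeatability = coverage_z * sd_diff,
    loa_lower = loa_lower,
    loa_upper = loa_upper,
    pct_within = 100 * mean(d >= loa_lower & d <= loa_upper),
    reliability_coefficient = reliability_coefficient(baseline, followup),
    diff_sign = diff_sign,
    pairs = tibble::tibble(subject_id = ids, baseline = unname(baseline),
                           followup = unname(followup), mean = unname(m),
                           diff = unname(d))
  )
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    paste0("Bland-Altman (%s), n = %d pairs (%d excluded)\n",
           "  mean difference %.3f, SD of differences %.3f\n",
           "  limits of agreement [%.3f, %.3f], repeatability %.3f\n",
           "  %.1f%% of differences within limits; reliability %.3f\n"),
    x$diff_sign, x$n, x$n_excluded, x$mean_diff, x$sd_diff,
    x$loa_lower, x$loa_upper, x$repeatability, x$pct_within,
    x$reliability_coefficient))
  invisible(x)
}

#' Reliability coefficient from within-person variance
#'
#' Interprets test-retest noise through a components-of-variance lens:
#' the within-person variance is estimated from the paired differences,
#' `sigma2_w = var(diff) / 2`, the total variance from the pooled
#' two-timepoint values, and the coefficient is
#' `1 - sigma2_w / sigma2_total`, floored at 0. A perfectly repeated,
#' non-constant measure scores 1; a measure whose variation is all
#' within-person noise scores 0.
#'
#' @param baseline,followup Paired numeric vectors (already aligned).
#' @return A value in \[0, 1\].
#' @export
reliability_coefficient <- function(baseline, followup) {
  ok <- stats::complete.cases(baseline, followup)
  baseline <- baseline[ok]
  followup <- followup[ok]
  if (length(baseline) < 3) {
    stop("reliability coefficient requires at least 3 complete pairs",
         call. = FALSE)
  }
  sigma2_w <- stats::var(followup - baseline) / 2
  sigma2_total <- stats::var(c(baseline, followup))
  if (sigma2_total == 0) {
    stop("total variance is zero; reliability coefficient undefined",
         call. = FALSE)
  }
  max(0, 1 - sigma2_w / sigma2_total)
}

#' Plot data for a Bland-Altman plot
#'
#' Per-subject (mean, difference) points plus the three reference lines
#' (mean difference and the two limits of agreement), exported as plain
#' tables so any plotting layer can draw them.
#'
#' @param result A `bland_altman` object.
#' @return A list with `points` (tibble: `subject_id`, `mean`, `diff`)
#'   and `lines` (tibble: `line`, `value`).
#' @export
bland_altman_plotdata <- function(result) {
  stopifnot(inherits(result, "bland_altman"))
  list(
    points = result$pairs[, c("subject_id", "mean", "diff")],
    lines = tibble::tibble(
      line = c("mean_diff", "loa_lower", "loa_upper"),
      value = c(result$mean_diff, result$loa_lower, result$loa_upper)
    )
  )
}
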