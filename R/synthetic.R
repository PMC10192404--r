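# Synthetic two-timepoint cohorts with known ground truth: latent diet
# quality driving ordinal picture-sort responses (with per-subject
# over/under-reporting bias), one-factor 4-point Likert scales with a
# configurable inter-item correlation, and adult reference measures with
# a programmed correlation to the latent.

#' Analytic Cronbach alpha of a one-factor scale
#'
#' Closed form for a scale of `k` exchangeable items with mean inter-item
#' correlation `rbar`: `k * rbar / (1 + (k - 1) * rbar)` (the
#' Spearman-Brown composite reliability).
#'
#' @param k Number of items (>= 2).
#' @param rbar Mean inter-item correlation in \[0, 1).
#' @return The analytic alpha.
#' @export
analytic_alpha <- function(k, rbar) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (rbar < 0 || rbar >= 1) stop("rbar must lie in [0, 1)", call. = FALSE)
  k * rbar / (1 + (k - 1) * rbar)
}

# Probabilist's Hermite polynomial values He_0..He_(nmax) at x.
hermite_values <- function(x, nmax) {
  out <- matrix(0, nrow = length(x), ncol = nmax + 1)
  out[, 1] <- 1
  if (nmax >= 1) out[, 2] <- x
  if (nmax >= 2) {
    for (n in 2:nmax) {
      out[, n + 1] <- x * out[, n] - (n - 1) * out[, n - 1]
    }
  }
  out
}

#' Correlation of threshold-discretized bivariate normal variables
#'
#' When a standard bivariate normal pair with correlation `rho` is cut at
#' common thresholds into ordered categories 1..K, the Pearson
#' correlation of the resulting ordinal pair is attenuated. This computes
#' it via the Hermite-series expansion of the step function: `Cov(rho) =
#' sum_n (sum_j phi(tau_j) He_{n-1}(tau_j))^2 / n! * rho^n`, divided by
#' the exact variance of the discretized margin.
#'
#' @param rho Latent correlation(s) in (-1, 1).
#' @param thresholds Increasing cut points on the standard normal scale.
#' @param nterms Series length (default 25, ample for |rho| < 0.95).
#' @return Pearson correlation(s) of the discretized pair.
#' @export
ordinal_corr <- function(rho, thresholds, nterms = 25) {
  he <- hermite_values(thresholds, nterms - 1)
  phi <- stats::dnorm(thresholds)
  coefs <- vapply(seq_len(nterms), function(n) {
    sum(phi * he[, n])^2 / factorial(n)
  }, numeric(1))
  probs <- diff(c(0, stats::pnorm(thresholds), 1))
  vals <- seq_along(probs)
  var_d <- sum(probs * vals^2) - sum(probs * vals)^2
  vapply(rho, function(r) sum(coefs * r^seq_len(nterms)) / var_d,
         numeric(1))
}

#' Latent correlation needed to hit a target ordinal correlation
#'
#' Inverts [ordinal_corr()] so a generator can pre-compensate for
#' discretization: items drawn with the returned latent correlation end
#' up with (approximately) the target Pearson correlation after being
#' cut at `thresholds`.
#'
#' @param target Desired correlation of the discretized pair, in \[0, 1).
#' @param thresholds Increasing cut points on the standard normal scale.
#' @return The latent correlation.
#' @export
latent_corr_for_target <- function(target, thresholds) {
  if (target == 0) return(0)
  upper <- 0.999
  if (ordinal_corr(upper, thresholds) < target) {
    stop("target ordinal correlation ", target,
         " is unattainable after discretization at these thresholds",
         call. = FALSE)
  }
  stats::uniroot(function(r) ordinal_corr(r, thresholds) - target,
                 c(0, upper), tol = 1e-9)$root
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the feasibility-study conditions: 25 children and 18
#' adults measured at two timepoints, follow-up completion of 72% and
#' 67%, adult FFQ F&V servings with mean 3.0 and SD 1.8, an obesogenic
#' index with mean 2.5 and SD 1.7, Likert scales targeting a mean
#' inter-item correlation of 0.35, a programmed correlation of 0.5
#' between reference measures and latent diet quality, moderate
#' per-subject reporting bias, and within-person test-retest noise of
#' 0.4 (on each instrument's measurement scale).
#'
#' @param n_children,n_adults Cohort sizes at baseline.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @param latent_sd SD of the latent diet-quality trait.
#' @param reporting_bias_sd SD of the per-subject over/under-reporting
#'   shift on the item-propensity scale.
#' @param target_interitem_r Target Pearson correlation between Likert
#'   items of a family after discretization, in \[0, 1).
#' @param sigma_within Within-person test-retest noise SD: added to item
#'   propensities at follow-up (picture-sort) and to measured servings /
#'   weekly frequencies at each timepoint (adult survey).
#' @param rho_index_reference Programmed correlation between the scored
#'   adult reference measures and the latent trait (positive for FFQ
#'   F&V, negative for the obesogenic index); also links the child
#'   psychosocial factor to the latent.
#' @param completion_child,completion_adult Proportion completing
#'   follow-up.
#' @param child_thresholds,adult_thresholds,likert_thresholds Cut points
#'   on the propensity scale for ordinal discretization.
#' @param loading_healthy,loading_unhealthy,loading_neutral Latent
#'   loadings of item propensities by item class.
#' @param intercept_healthy,intercept_other,intercept_sd Mean (by item
#'   class) and SD of the per-item propensity intercepts; the defaults
#'   put healthy items at roughly 1.5-1.7 servings/day per five-item
#'   component and the healthy-to-total ratio near 0.25-0.3, the intake
#'   levels typical of a child cohort in this setting.
#' @param ffq_mean,ffq_sd Marginal mean and SD of true FFQ F&V total
#'   servings/day (lognormal).
#' @param obesogenic_mean,obesogenic_sd Marginal mean and SD of the true
#'   obesogenic index (lognormal).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_children = 25,
                             n_adults = 18,
                             seed = 1,
                             latent_sd = 1,
                             reporting_bias_sd = 0.3,
                             target_interitem_r = 0.35,
                             sigma_within = 0.4,
                             rho_index_reference = 0.5,
                             completion_child = 0.72,
                             completion_adult = 0.67,
                             child_thresholds = c(-0.4, 1.2, 1.75),
                             adult_thresholds = c(-0.9, -0.1, 0.8, 1.5),
                             likert_thresholds = stats::qnorm(c(0.25, 0.5,
                                                                0.75)),
                             loading_healthy = 0.7,
                             loading_unhealthy = -0.7,
                             loading_neutral = 0.15,
                             intercept_healthy = -0.45,
                             intercept_other = 0,
                             intercept_sd = 0.3,
                             ffq_mean = 3.0, ffq_sd = 1.8,
                             obesogenic_mean = 2.5, obesogenic_sd = 1.7) {
  cfg <- as.list(environment())
  check <- function(ok, field, what) {
    if (!ok) stop("invalid synthetic_config field '", field, "': ", what,
                  call. = FALSE)
  }
  check(n_children >= 0 && n_children == round(n_children), "n_children",
        "must be a non-negative integer")
  check(n_adults >= 0 && n_adults == round(n_adults), "n_adults",
        "must be a non-negative integer")
  check(is.numeric(seed) && length(seed) == 1, "seed",
        "must be a single integer")
  check(latent_sd >= 0, "latent_sd", "must be >= 0")
  check(reporting_bias_sd >= 0, "reporting_bias_sd", "must be >= 0")
  check(sigma_within >= 0, "sigma_within", "must be >= 0")
  check(target_interitem_r >= 0 && target_interitem_r < 1,
        "target_interitem_r", "must lie in [0, 1)")
  check(abs(rho_index_reference) < 1, "rho_index_reference",
        "must lie in (-1, 1)")
  check(completion_child > 0 && completion_child <= 1, "completion_child",
        "must lie in (0, 1]")
  check(completion_adult > 0 && completion_adult <= 1, "completion_adult",
        "must lie in (0, 1]")
  for (f in c("child_thresholds", "adult_thresholds", "likert_thresholds")) {
    check(!is.unsorted(cfg[[f]], strictly = TRUE), f,
          "must be strictly increasing")
  }
  check(ffq_mean > 0 && ffq_sd > 0, "ffq_mean", "must be positive")
  check(obesogenic_mean > 0 && obesogenic_sd > 0, "obesogenic_mean",
        "must be positive")
  class(cfg) <- "synthetic_config"
  cfg
}

# meanlog/sdlog of a lognormal with the given mean and sd.
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Attenuation of corr(measured reference, latent) induced by the
# lognormal transform and additive measurement noise; the generator
# divides the programmed rho by this so the scored measure correlates
# with the latent at the programmed value.
reference_attenuation <- function(sdlog, marginal_sd, sigma_within) {
  c_lognormal <- sdlog / sqrt(exp(sdlog^2) - 1)
  c_noise <- marginal_sd / sqrt(marginal_sd^2 + sigma_within^2)
  c_lognormal * c_noise
}

ffq_weights <- c(
  ffq_juice = 0.15, ffq_fruit = 0.45, ffq_green_salad = 0.12,
  ffq_other_potatoes = 0.08, ffq_beans = 0.10, ffq_other_veg = 0.10
)
obesogenic_weights <- c(fast_food = 0.8, french_fries = 1.1, soda = 1.1)

# Ordinal picture-sort responses for one role at both timepoints.
picture_sort_block <- function(ids, latent_std, bias, registry, cfg,
                               dialect, thresholds, completers) {
  n <- length(ids)
  items <- registry$item_id
  k <- length(items)
  loading <- ifelse(
    registry$healthy, cfg$loading_healthy,
    ifelse(registry$ahei_component %in% c("ssb_juice", "red_processed_meat"),
           cfg$loading_unhealthy, cfg$loading_neutral))
  intercept <- stats::rnorm(
    k, ifelse(registry$healthy, cfg$intercept_healthy, cfg$intercept_other),
    cfg$intercept_sd)
  e <- matrix(stats::rnorm(n * k), n, k)
  eta <- matrix(stats::rnorm(n * k, 0, cfg$sigma_within), n, k)
  base_prop <- outer(latent_std, loading) + bias +
    matrix(intercept, n, k, byrow = TRUE) + e
  fup_prop <- base_prop + eta
  cut_one <- function(p) {
    dialect$categories[findInterval(p, thresholds) + 1L]
  }
  long <- function(prop, timepoint, keep_ids) {
    keep <- ids %in% keep_ids
    if (!any(keep)) return(NULL)
    tibble::tibble(
      subject_id = rep(ids[keep], times = k),
      role = dialect$name,
      timepoint = timepoint,
      item_id = rep(items, each = sum(keep)),
      response = cut_one(as.vector(prop[keep, , drop = FALSE]))
    )
  }
  dplyr::bind_rows(long(base_prop, "baseline", ids),
                   long(fup_prop, "followup", completers))
}

#' Generate a synthetic two-timepoint cohort
#'
#' Children and adults carry a latent diet-quality trait `T ~ N(0,
#' latent_sd)` and a per-subject reporting bias. Picture-sort item
#' propensities are `intercept + loading * T_std + bias + noise`, with
#' healthy items loading positively and SSB / red-processed-meat items
#' negatively, discretized at fixed thresholds into the dialect's
#' categories; follow-up adds within-person noise to the same propensity
#' draw, so `sigma_within = 0` reproduces baseline exactly. Likert items
#' follow a one-factor model per instrument family whose latent
#' inter-item correlation is pre-compensated with
#' [latent_corr_for_target()] so the discretized items hit
#' `target_interitem_r`, making the analytic alpha of every scale
#' computable in closed form. Adult FFQ and obesogenic measures are
#' lognormal with the configured marginal moments and are
#' attenuation-compensated so the scored measure correlates with the
#' latent at `rho_index_reference` (+ for FFQ, - for obesogenic); each
#' timepoint adds measurement noise of SD `sigma_within`, so the paired
#' difference SD is `sqrt(2) * sigma_within`.
#'
#' @param config A [synthetic_config()].
#' @param registry Food registry used for the picture-sort items.
#' @param scales Psychosocial scale definitions.
#' @param ffq_items FFQ item table.
#' @return A list of class `synthetic_cohort` with elements `responses`,
#'   `likert`, `adult_survey`, `registry`, `scales`, `dialects`,
#'   `ffq_items`, `ground_truth`, `config`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            registry = default_registry(),
                            scales = default_scales(),
                            ffq_items = default_ffq_items()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  dialects <- default_dialects()

  child_ids <- if (cfg$n_children > 0)
    sprintf("C%04d", seq_len(cfg$n_children)) else character()
  adult_ids <- if (cfg$n_adults > 0)
    sprintf("A%04d", seq_len(cfg$n_adults)) else character()

  draw_latents <- function(ids) {
    n <- length(ids)
    tibble::tibble(
      subject_id = ids,
      latent = stats::rnorm(n, 0, cfg$latent_sd),
      bias = stats::rnorm(n, 0, cfg$reporting_bias_sd)
    )
  }
  gt_children <- draw_latents(child_ids)
  gt_adults <- draw_latents(adult_ids)
  std <- function(x) if (cfg$latent_sd > 0) x / cfg$latent_sd else x * 0

  child_completers <- sample(child_ids,
                             round(cfg$n_children * cfg$completion_child))
  adult_completers <- sample(adult_ids,
                             round(cfg$n_adults * cfg$completion_adult))

  # --- picture-sort responses -------------------------------------------
  responses <- dplyr::bind_rows(
    if (cfg$n_children > 0) {
      picture_sort_block(
        child_ids, std(gt_children$latent), gt_children$bias,
        registry[!registry$is_alcohol, ], cfg, dialects$child,
        cfg$child_thresholds, child_completers)
    },
    if (cfg$n_adults > 0) {
      picture_sort_block(
        adult_ids, std(gt_adults$latent), gt_adults$bias,
        registry, cfg, dialects$adult,
        cfg$adult_thresholds, adult_completers)
    }
  )

  # --- child Likert scales ----------------------------------------------
  likert <- tibble::tibble(subject_id = character(), timepoint = character(),
                           item_id = character(), response = integer())
  if (cfg$n_children > 0) {
    item_tbl <- default_scale_items()
    item_tbl <- item_tbl[item_tbl$item_id %in% scales$item_id, ]
    r_latent <- latent_corr_for_target(cfg$target_interitem_r,
                                       cfg$likert_thresholds)
    w <- sqrt(r_latent)
    rho_c <- cfg$rho_index_reference
    n <- cfg$n_children
    blocks <- list()
    for (fam in unique(item_tbl$family)) {
      fam_items <- item_tbl$item_id[item_tbl$family == fam]
      f_factor <- rho_c * std(gt_children$latent) +
        sqrt(1 - rho_c^2) * stats::rnorm(n)
      for (tp in c("baseline", "followup")) {
        eps <- matrix(stats::rnorm(n * length(fam_items)), n,
                      length(fam_items))
        y <- w * f_factor + sqrt(1 - w^2) * eps
        resp <- matrix(findInterval(y, cfg$likert_thresholds) + 1L,
                       nrow = n, ncol = length(fam_items))
        keep_ids <- if (tp == "baseline") child_ids else child_completers
        keep <- child_ids %in% keep_ids
        if (!any(keep)) next
        blocks[[paste(fam, tp)]] <- tibble::tibble(
          subject_id = rep(child_ids[keep], times = length(fam_items)),
          timepoint = tp,
          item_id = rep(fam_items, each = sum(keep)),
          response = as.integer(resp[keep, , drop = FALSE])
        )
      }
    }
    likert <- dplyr::bind_rows(blocks)
  }

  # --- adult reference measures -----------------------------------------
  adult_survey <- tibble::tibble(
    subject_id = character(), timepoint = character(), measure = character(),
    item_id = character(), value = numeric())
  ffq_true <- obeso_true <- numeric()
  if (cfg$n_adults > 0) {
    n <- cfg$n_adults
    t_std <- std(gt_adults$latent)
    rho <- cfg$rho_index_reference

    lp_ffq <- lognormal_params(cfg$ffq_mean, cfg$ffq_sd)
    att_ffq <- reference_attenuation(lp_ffq$sdlog, cfg$ffq_sd,
                                     cfg$sigma_within)
    rho_inner <- rho / att_ffq
    if (abs(rho_inner) >= 1) {
      stop("rho_index_reference = ", rho, " is unattainable for the FFQ ",
           "under the configured noise; reduce |rho| or sigma_within",
           call. = FALSE)
    }
    z <- rho_inner * t_std + sqrt(1 - rho_inner^2) * stats::rnorm(n)
    ffq_true <- exp(lp_ffq$meanlog + lp_ffq$sdlog * z)

    lp_ob <- lognormal_params(cfg$obesogenic_mean, cfg$obesogenic_sd)
    att_ob <- reference_attenuation(lp_ob$sdlog, cfg$obesogenic_sd,
                                    cfg$sigma_within)
    rho_inner_ob <- -rho / att_ob
    if (abs(rho_inner_ob) >= 1) {
      stop("rho_index_reference = ", rho, " is unattainable for the ",
           "obesogenic index under the configured noise", call. = FALSE)
    }
    zo <- rho_inner_ob * t_std + sqrt(1 - rho_inner_ob^2) * stats::rnorm(n)
    obeso_true <- exp(lp_ob$meanlog + lp_ob$sdlog * zo)

    fries_true <- stats::rlnorm(n, log(0.2), 0.6)

    survey_block <- function(tp, keep_ids) {
      keep <- adult_ids %in% keep_ids
      if (!any(keep)) return(NULL)
      m <- sum(keep)
      ffq_rows <- dplyr::bind_rows(lapply(names(ffq_weights), function(it) {
        wj <- ffq_weights[[it]]
        tibble::tibble(
          subject_id = adult_ids[keep], timepoint = tp, measure = "ffq",
          item_id = it,
          value = pmax(0, wj * ffq_true[keep] +
                         stats::rnorm(m, 0, cfg$sigma_within * sqrt(wj)))
        )
      }))
      fries_rows <- tibble::tibble(
        subject_id = adult_ids[keep], timepoint = tp, measure = "ffq",
        item_id = "ffq_fries",
        value = pmax(0, fries_true[keep] + stats::rnorm(m, 0, 0.1))
      )
      ob_rows <- dplyr::bind_rows(lapply(names(obesogenic_weights),
                                         function(it) {
        wj <- obesogenic_weights[[it]]
        tibble::tibble(
          subject_id = adult_ids[keep], timepoint = tp,
          measure = "obesogenic", item_id = it,
          value = pmax(0, wj * obeso_true[keep] +
                         stats::rnorm(m, 0, cfg$sigma_within * sqrt(3)))
        )
      }))
      dplyr::bind_rows(ffq_rows, fries_rows, ob_rows)
    }
    adult_survey <- dplyr::bind_rows(
      survey_block("baseline", adult_ids),
      survey_block("followup", adult_completers))
  }

  # --- ground truth ------------------------------------------------------
  scale_k <- scales |>
    dplyr::count(.data$scale_id, name = "k")
  gt_alpha <- tibble::tibble(
    scale_id = scale_k$scale_id,
    k = scale_k$k,
    target_r = cfg$target_interitem_r,
    alpha = vapply(scale_k$k, analytic_alpha, numeric(1),
                   rbar = cfg$target_interitem_r)
  )
  gt_adults$ffq_true <- if (length(ffq_true) > 0) ffq_true else numeric()
  gt_adults$obesogenic_true <-
    if (length(obeso_true) > 0) obeso_true else numeric()

  structure(
    list(
      responses = responses,
      likert = likert,
      adult_survey = adult_survey,
      registry = registry,
      scales = scales,
      dialects = dialects,
      ffq_items = ffq_items,
      ground_truth = list(
        children = gt_children,
        adults = gt_adults,
        analytic_alpha = gt_alpha,
        sigma_within = cfg$sigma_within,
        rho_index_reference = cfg$rho_index_reference,
        child_completers = sort(child_completers),
        adult_completers = sort(adult_completers)
      ),
      config = cfg
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic picture-sort cohort (seed %d)\n",
           "  children: %d baseline, %d follow-up\n",
           "  adults:   %d baseline, %d follow-up\n",
           "  %d picture-sort responses, %d Likert responses, ",
           "%d adult survey rows\n"),
    x$config$seed, x$config$n_children,
    length(x$ground_truth$child_completers),
    x$config$n_adults, length(x$ground_truth$adult_completers),
    nrow(x$responses), nrow(x$likert), nrow(x$adult_survey)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits exactly the formats the loaders consume: `responses.csv`,
#' `likert.csv`, `adult_survey.csv`, `registry.json`, and
#' `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$likert, file.path(dir, "likert.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$adult_survey, file.path(dir, "adult_survey.csv"),
                   row.names = FALSE)
  write_food_registry(cohort$registry, file.path(dir, "registry.json"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
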