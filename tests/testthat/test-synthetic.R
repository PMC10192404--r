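test_that("analytic alpha closed form", {
  expect_equal(analytic_alpha(3, 0.5), 0.75)
  expect_equal(analytic_alpha(2, 1 / 3), 0.5)
  expect_equal(analytic_alpha(6, 0), 0)
  expect_error(analytic_alpha(1, 0.5), "at least 2")
  expect_error(analytic_alpha(3, 1), "\\[0, 1\\)")
})

test_that("ordinal attenuation is monotone and invertible", {
  thr <- qnorm(c(0.25, 0.5, 0.75))
  expect_equal(ordinal_corr(0, thr), 0)
  rr <- ordinal_corr(c(0.2, 0.5, 0.8), thr)
  expect_true(all(diff(rr) > 0))
  expect_true(all(rr < c(0.2, 0.5, 0.8)))  # discretization attenuates
  for (target in c(0.2, 0.35, 0.6)) {
    lat <- latent_corr_for_target(target, thr)
    expect_gt(lat, target)
    expect_equal(ordinal_corr(lat, thr), target, tolerance = 1e-6)
  }
  expect_error(latent_corr_for_target(0.995, thr), "unattainable")
})

test_that("the empirical ordinal correlation matches the series formula", {
  set.seed(41)
  thr <- qnorm(c(0.25, 0.5, 0.75))
  rho <- 0.6
  n <- 50000
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  dx <- findInterval(x, thr)
  dy <- findInterval(y, thr)
  expect_equal(cor(dx, dy), ordinal_corr(rho, thr), tolerance = 0.02)
})

test_that("cohort generation is deterministic in the seed", {
  cfg <- synthetic_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$likert, b$likert)
  expect_identical(a$adult_survey, b$adult_survey)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_cohort(synthetic_config(seed = 8))
  expect_false(identical(a$responses, c$responses))
})

test_that("default cohort has the study's shape", {
  co <- generate_cohort(synthetic_config(seed = 7))
  cr <- completion_rates(co$responses)
  expect_equal(cr$n_baseline[cr$role == "child"], 25)
  expect_equal(cr$n_followup[cr$role == "child"], 18)
  expect_equal(cr$n_baseline[cr$role == "adult"], 18)
  expect_equal(cr$n_followup[cr$role == "adult"], 12)
  # children never see alcohol cards
  reg <- co$registry
  child_items <- unique(co$responses$item_id[co$responses$role == "child"])
  expect_false(any(child_items %in% reg$item_id[reg$is_alcohol]))
  # every generated label is valid for its dialect
  out <- validate_responses(co$responses, reg, co$dialects)
  expect_equal(nrow(out$report$errors), 0)
  # Likert responses live on the 4-point scale
  expect_true(all(co$likert$response %in% 1:4))
})

test_that("zero within-person noise reproduces baseline at follow-up", {
  co <- generate_cohort(synthetic_config(seed = 5, sigma_within = 0))
  idx <- score_diets(co$responses, co$registry, co$dialects)
  base <- idx[idx$timepoint == "baseline", ]
  fup <- idx[idx$timepoint == "followup", ]
  merged <- merge(base, fup, by = c("subject_id", "role"))
  expect_equal(merged$modified_ahei_total.x, merged$modified_ahei_total.y)
  expect_equal(merged$total_freq.x, merged$total_freq.y)
})

test_that("no response category is degenerate at the default config", {
  co <- generate_cohort(synthetic_config(n_children = 400, n_adults = 400,
                                         seed = 13))
  for (role in c("child", "adult")) {
    resp <- co$responses[co$responses$role == role &
                           co$responses$timepoint == "baseline", ]
    shares <- table(resp$response) / nrow(resp)
    expect_setequal(names(shares), co$dialects[[role]]$categories)
    expect_true(all(shares >= 0.05))
  }
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synthetic_config(latent_sd = -1), "latent_sd")
  expect_error(synthetic_config(target_interitem_r = 1), "target_interitem_r")
  expect_error(synthetic_config(rho_index_reference = 1.2),
               "rho_index_reference")
  expect_error(synthetic_config(completion_child = 0), "completion_child")
  expect_error(synthetic_config(n_children = 2.5), "n_children")
  expect_error(synthetic_config(child_thresholds = c(1, 0, 2)),
               "child_thresholds")
})

test_that("ground truth records the analytic alpha targets", {
  co <- generate_cohort(synthetic_config(seed = 3, target_interitem_r = 0.5))
  ga <- co$ground_truth$analytic_alpha
  expect_equal(ga$alpha[ga$scale_id == "se_fruit_eat"], 0.75)  # k = 3
  expect_equal(ga$alpha[ga$scale_id == "se_fv_8"],
               analytic_alpha(8, 0.5))
})

test_that("scored scales recover the analytic alpha at scale", {
  co <- generate_cohort(synthetic_config(n_children = 1000, n_adults = 0,
                                         seed = 17))
  lk <- co$likert[co$likert$timepoint == "baseline", ]
  ids <- default_scales()
  for (sid in c("se_fv_5", "tendency_fv")) {
    items <- ids$item_id[ids$scale_id == sid]
    wide <- tidyr::pivot_wider(lk[lk$item_id %in% items, ],
                               names_from = "item_id",
                               values_from = "response")
    a <- cronbach_alpha(as.matrix(wide[, items]))
    target <- co$ground_truth$analytic_alpha$alpha[
      co$ground_truth$analytic_alpha$scale_id == sid]
    expect_equal(a, target, tolerance = 0.05)
  }
})

test_that("the ratio index resists reporting bias better than raw totals", {
  corr_with_latent <- function(bias_sd) {
    co <- generate_cohort(synthetic_config(
      n_children = 800, n_adults = 0, seed = 19,
      reporting_bias_sd = bias_sd, completion_child = 1))
    idx <- score_diets(co$responses, co$registry, co$dialects)
    idx <- idx[idx$timepoint == "baseline", ]
    gt <- co$ground_truth$children
    ord <- match(gt$subject_id, idx$subject_id)
    c(ratio = cor(idx$ratio_healthy_total[ord], gt$latent,
                  use = "complete.obs"),
      healthy_freq = cor(idx$healthy_freq[ord], gt$latent))
  }
  low <- corr_with_latent(0.05)
  high <- corr_with_latent(1.5)
  # both degrade, but the ratio's correlation with true diet quality
  # degrades less than the raw healthy-frequency total's
  expect_lt(high[["healthy_freq"]], low[["healthy_freq"]])
  expect_lt(low[["ratio"]] - high[["ratio"]],
            low[["healthy_freq"]] - high[["healthy_freq"]])
})

test_that("cohorts round-trip through the plain-text interchange files", {
  co <- generate_cohort(synthetic_config(seed = 29))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("responses.csv", "likert.csv", "adult_survey.csv",
                    "registry.json", "ground_truth.json"))
  back <- load_response_table(file.path(dir, "responses.csv"),
                              load_food_registry(file.path(dir,
                                                           "registry.json")))
  expect_equal(nrow(back$report$errors), 0)
  expect_equal(nrow(back$records), nrow(co$responses))
})
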