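# Shared fixtures: small response tables and independent oracles used to
# cross-check the scoring implementations.

make_responses <- function(item_id, response, subject_id = "S1",
                           role = "child", timepoint = "baseline") {
  tibble::tibble(subject_id = subject_id, role = role,
                 timepoint = timepoint, item_id = item_id,
                 response = response)
}

# Brute-force component accumulation written directly from the registry
# table, independent of the vectorized implementation.
oracle_components <- function(records, registry, dialect,
                              include_salad = TRUE) {
  acc <- c(vegetables = 0, fruit_excl_juice = 0, whole_grains = 0,
           nuts_legumes = 0, ssb_juice = 0, red_processed_meat = 0,
           healthy_freq = 0, total_freq = 0)
  for (i in seq_len(nrow(records))) {
    it <- registry[registry$item_id == records$item_id[i], ]
    s <- unname(dialect$servings_per_day[[records$response[i]]])
    comp <- it$ahei_component
    if (comp == "vegetables" && !it$is_potato &&
        (include_salad || !it$is_salad)) {
      acc["vegetables"] <- acc["vegetables"] + s
    }
    if (comp == "fruit" && !it$is_fruit_juice) {
      acc["fruit_excl_juice"] <- acc["fruit_excl_juice"] + s
    }
    if (comp == "whole_grains") acc["whole_grains"] <- acc["whole_grains"] + s
    if (comp == "nuts_legumes") acc["nuts_legumes"] <- acc["nuts_legumes"] + s
    if (comp == "ssb_juice") acc["ssb_juice"] <- acc["ssb_juice"] + s
    if (comp == "red_processed_meat") {
      acc["red_processed_meat"] <- acc["red_processed_meat"] + s
    }
    if (it$healthy) acc["healthy_freq"] <- acc["healthy_freq"] + s
    if (!it$is_alcohol) acc["total_freq"] <- acc["total_freq"] + s
  }
  acc
}

# Random child response set over a random subset of registry items.
random_child_responses <- function(registry, n_items = 10) {
  items <- sample(registry$item_id, n_items)
  make_responses(items,
                 sample(child_dialect()$categories, n_items,
                        replace = TRUE))
}

# Continuous compound-symmetric one-factor data: k items with pairwise
# correlation rbar.
cs_matrix <- function(n, k, rbar) {
  f <- stats::rnorm(n)
  sapply(seq_len(k), function(j) {
    sqrt(rbar) * f + sqrt(1 - rbar) * stats::rnorm(n)
  })
}

# Brute-force Cronbach alpha from the covariance matrix.
oracle_alpha <- function(m) {
  s <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(s)) / sum(s))
}

# Brute-force Pearson r and two-sided p from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# p-value implied by a correlation at sample size n (used to rebuild
# printed correlation-table rows).
p_from_r <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}
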