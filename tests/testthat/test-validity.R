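test_that("pearson_with_p reproduces hand-checked correlations", {
  x <- c(1, 2, 3)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_equal(pearson_with_p(x, c(1, 2, 4))$r, 0.982, tolerance = 1e-3)
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "constant input")
})

test_that("pearson_with_p matches a first-principles oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    got <- pearson_with_p(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$n, n)
  }
})

test_that("incomplete pairs are dropped pairwise", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, NA, 8, 10)
  got <- pearson_with_p(x, y)
  expect_equal(got$n, 3)
  expect_equal(got$r, 1)
})

test_that("the correlation matrix covers all index-reference pairs", {
  set.seed(22)
  n <- 25
  idx <- tibble::tibble(subject_id = as.character(1:n))
  for (nm in paste0("index", 1:7)) idx[[nm]] <- rnorm(n)
  idx$index_dup <- idx$index1
  ref <- tibble::tibble(subject_id = as.character(1:n))
  for (nm in paste0("ref", 1:4)) ref[[nm]] <- rnorm(n)

  out <- convergent_validity_matrix(idx[, 1:8], ref)
  expect_equal(nrow(out), 28)

  out1 <- convergent_validity_matrix(idx[, c("subject_id", "index1")],
                                     ref[, c("subject_id", "ref1")])
  expect_equal(nrow(out1), 1)

  # a duplicated index yields identical correlations under both names
  out_dup <- convergent_validity_matrix(
    idx[, c("subject_id", "index1", "index_dup")], ref)
  r1 <- out_dup$r[out_dup$var_x == "index1"]
  r2 <- out_dup$r[out_dup$var_x == "index_dup"]
  expect_equal(r1, r2)

  ref2 <- ref
  ref2$subject_id <- paste0("Z", ref2$subject_id)
  expect_error(convergent_validity_matrix(idx, ref2), "no overlapping")

  # constant columns surface as NA rows rather than vanishing
  idx$flat <- 1
  out_flat <- convergent_validity_matrix(idx[, c("subject_id", "flat")], ref)
  expect_true(all(is.na(out_flat$r)))
})

test_that("significance flags match the reporting thresholds", {
  expect_equal(significance_flag(c(0.0005, 0.01, 0.03, 0.09, 0.2)),
               c("p<0.001", "p<=0.01", "p<0.05", "p<0.1", ""))
})

test_that("retention requires p <= 0.1 and the expected sign", {
  # rebuild printed-style rows: r = 0.30 at n = 25 is p > 0.1 -> dropped,
  # r = 0.47 at n = 18 is p < 0.05 -> retained
  rows <- tibble::tibble(
    var_x = c("fruit_score", "modified_ahei_total", "ratio"),
    var_y = c("se_fv_5", "ffq_fv", "ffq_fv"),
    r = c(0.30, 0.47, 0.9),
    p = c(p_from_r(0.30, 25), p_from_r(0.47, 18), 0.001),
    n = c(25, 18, 18))
  expect_gt(rows$p[1], 0.1)
  expect_lt(rows$p[2], 0.05)

  spec <- tibble::tibble(reference = c("se_fv_5", "ffq_fv"),
                         expected_sign = c("+", "+"))
  dec <- retention_filter(rows, spec)
  expect_false(dec$retained[dec$index == "fruit_score"])
  expect_true(dec$retained[dec$index == "modified_ahei_total"])

  # strong correlation with the wrong sign is never retained
  rows$r[3] <- -0.9
  dec <- retention_filter(rows, spec)
  expect_false(dec$retained[dec$index == "ratio"])

  # boundary: p exactly at the threshold passes ("P > 0.1" is dropped)
  rows2 <- tibble::tibble(var_x = "i", var_y = "se_fv_5", r = 0.4,
                          p = 0.1, n = 25)
  dec2 <- retention_filter(rows2, spec[1, ])
  expect_true(dec2$retained)

  expect_error(retention_filter(rows, tibble::tibble(
    reference = "nope", expected_sign = "+")), "not present")
  expect_error(retention_filter(rows, tibble::tibble(
    reference = "ffq_fv", expected_sign = "urgh")), "'\\+' or '-'")
})

test_that("an adult index is retained if either reference passes", {
  rows <- tibble::tibble(
    var_x = "ratio", var_y = c("ffq_fv", "obesogenic"),
    r = c(0.1, -0.6), p = c(0.8, 0.02), n = 18)
  spec <- tibble::tibble(reference = c("ffq_fv", "obesogenic"),
                         expected_sign = c("+", "-"))
  dec <- retention_filter(rows, spec)
  expect_true(all(dec$retained))
  expect_equal(sum(dec$passes), 1)
})

test_that("estimated r recovers a programmed latent correlation", {
  set.seed(23)
  rho <- 0.6
  n <- 10000
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(pearson_with_p(x, y)$r, rho, tolerance = 0.05)
})
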