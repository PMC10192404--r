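se5 <- function() {
  sc <- default_scales()
  sc[sc$scale_id == "se_fv_5", ]
}

test_that("scale means and rescaling follow the 4-point Likert rules", {
  sc <- se5()
  all4 <- setNames(rep(4, 5), sc$item_id)
  out <- scale_mean(all4, sc)
  expect_equal(out$mean_score, 4)
  expect_equal(out$rescaled, 1)

  all1 <- setNames(rep(1, 5), sc$item_id)
  expect_equal(scale_mean(all1, sc)$rescaled, 0)  # (1-1)/3

  three <- setNames(c(2, 3, 3), sc$item_id[1:3])
  expect_equal(scale_mean(three, sc)$mean_score, 2.667, tolerance = 1e-3)

  # subscale filter restricts before averaging
  vals <- setNames(c(4, 4, 4, 1, 1), sc$item_id)
  expect_equal(scale_mean(vals, sc, subscale = "fruit")$mean_score, 4)
  expect_equal(scale_mean(vals, sc, subscale = "vegetable")$mean_score, 1)

  # nothing answered: missing score, not an error or a number
  none <- scale_mean(setNames(numeric(), character()), sc)
  expect_true(is.na(none$mean_score))
  expect_equal(none$n_items_answered, 0)

  expect_error(scale_mean(setNames(5, sc$item_id[1]), sc), "outside")
})

test_that("rescaling is affine, order preserving, and in [0, 1]", {
  x <- c(1, 1.7, 2.5, 4)
  r <- rescale_score(x)
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(order(r), order(x))
  expect_equal(r, (x - 1) / 3)
  expect_error(rescale_score(1, 4, 4), "exceed")
})

test_that("cronbach_alpha matches the covariance-matrix oracle", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(sample(1:4, 20, replace = TRUE), nrow = 5, ncol = 4)
    if (var(rowSums(m)) == 0) next
    expect_equal(cronbach_alpha(m), oracle_alpha(m), tolerance = 1e-9)
  }
})

test_that("cronbach_alpha limit cases behave", {
  # perfectly correlated items
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  # independent items: alpha near zero
  set.seed(8)
  m <- matrix(rnorm(4000 * 3), ncol = 3)
  expect_lt(abs(cronbach_alpha(m)), 0.06)
  # degenerate inputs
  expect_error(cronbach_alpha(matrix(1:10, ncol = 1)), "2 items")
  expect_error(cronbach_alpha(matrix(1:4, ncol = 2)), "3 subjects")
  expect_error(cronbach_alpha(matrix(c(1, 2, 3, 3, 2, 1), ncol = 2)),
               "degenerate")
})

test_that("alpha converges to the one-factor closed form", {
  set.seed(9)
  m <- cs_matrix(5000, 4, 0.4)
  expect_equal(cronbach_alpha(m), analytic_alpha(4, 0.4), tolerance = 0.03)
})

test_that("alpha_if_deleted recomputes alpha per left-out item", {
  set.seed(10)
  m <- cs_matrix(50, 4, 0.5)
  colnames(m) <- paste0("it", 1:4)
  loo <- alpha_if_deleted(m)
  expect_named(loo, colnames(m))
  expect_equal(loo[["it2"]], cronbach_alpha(m[, -2]))
  expect_error(alpha_if_deleted(m[, 1:2]), "at least 3 items")
})

test_that("the removal rule is relative improvement over baseline", {
  # printed pair: 0.31 improving to 0.67 removes (+116% > 30%)
  dec <- removal_decision(0.31, c(a = 0.20, b = 0.67, c = 0.25))
  expect_true(dec$remove)
  expect_equal(dec$removed_item, "b")
  expect_equal(dec$alpha_after, 0.67)
  expect_equal(dec$relative_improvement, (0.67 - 0.31) / 0.31,
               tolerance = 1e-12)

  # printed pair: 0.60 to 0.65 retains (+8% < 30%)
  dec <- removal_decision(0.60, c(a = 0.65, b = 0.55))
  expect_false(dec$remove)
  expect_true(is.na(dec$removed_item))

  # no item helps: no removal
  dec <- removal_decision(0.70, c(a = 0.60, b = 0.65))
  expect_false(dec$remove)

  # non-positive baseline still yields a flagged decision
  dec <- removal_decision(-0.05, c(a = 0.40, b = 0.10))
  expect_true(dec$baseline_nonpositive)
  expect_true(dec$remove)

  # ties break to the first item in scale order, deterministically
  dec <- removal_decision(0.30, c(a = 0.50, b = 0.50))
  expect_equal(dec$removed_item, "a")
})

test_that("alpha_item_removal drops an incoherent item from a scale", {
  set.seed(11)
  f <- rnorm(200)
  m <- cbind(x1 = f + rnorm(200, 0, 0.6), x2 = f + rnorm(200, 0, 0.6),
             x3 = f + rnorm(200, 0, 0.6), x4 = -f + rnorm(200, 0, 0.6))
  rep <- alpha_item_removal(m)
  expect_equal(rep$removed_item, "x4")
  expect_gt(rep$alpha_after, rep$alpha)

  # a coherent scale keeps all items
  rep2 <- alpha_item_removal(m[, 1:3])
  expect_true(is.na(rep2$removed_item))

  # two-item scales have no removal candidates
  rep3 <- alpha_item_removal(m[, 1:2])
  expect_null(rep3$loo_alphas)
  expect_true(is.na(rep3$removed_item))
})

test_that("coefficient of variation is scale-shift sensitive by design", {
  expect_equal(coefficient_of_variation(rep(0.4, 10)), 0)
  expect_equal(coefficient_of_variation(c(0.2, 0.4)), 0.471,
               tolerance = 1e-3)
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
  raw <- c(2, 3, 3, 4)
  expect_false(isTRUE(all.equal(coefficient_of_variation(raw),
                                coefficient_of_variation(rescale_score(raw)))))
})

test_that("score_scales aggregates a long Likert table per scale", {
  sc <- default_scales()
  lk <- tibble::tibble(
    subject_id = "S1", timepoint = "baseline",
    item_id = sc$item_id[sc$scale_id == "se_fv_8"],
    response = c(4, 4, 4, 4, 2, 2, 2, 2))
  out <- score_scales(lk, sc)
  expect_equal(out$mean_score[out$scale_id == "se_fruit_all"], 4)
  expect_equal(out$mean_score[out$scale_id == "se_veg_all"], 2)
  expect_equal(out$mean_score[out$scale_id == "se_fv_8"], 3)
  expect_equal(out$rescaled[out$scale_id == "se_fv_8"], 2 / 3)
})

test_that("default scales match the instrument's sizes and subscales", {
  sc <- default_scales()
  sizes <- table(sc$scale_id)
  expect_equal(as.integer(sizes[c("tendency_fv", "se_fruit_eat",
                                  "se_veg_eat", "se_fv_5", "se_fv_8")]),
               c(6L, 3L, 2L, 5L, 8L))
  s8 <- sc[sc$scale_id == "se_fv_8", ]
  expect_equal(sum(s8$subscale == "fruit"), 4)
  expect_equal(sum(s8$subscale == "vegetable"), 4)
})
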