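test_that("component servings honour the exclusion rules", {
  reg <- default_registry()

  # never eaten anything: all zero
  all_never <- make_responses(reg$item_id, "never")
  cs <- component_servings(all_never)
  expect_equal(cs$total_freq, 0)
  expect_equal(cs$healthy_freq, 0)
  expect_equal(cs$vegetables + cs$fruit_excl_juice + cs$ssb_juice, 0)

  # one fruit item once a day
  cs <- component_servings(make_responses("apple", "once a day"))
  expect_equal(cs$fruit_excl_juice, 1)
  expect_equal(cs$total_freq, 1)
  expect_equal(cs$healthy_freq, 1)

  # fruit daily + fruit juice daily: juice goes to SSB, not fruit
  cs <- component_servings(make_responses(c("apple", "fruit_juice"),
                                          c("once a day", "once a day")))
  expect_equal(cs$fruit_excl_juice, 1)
  expect_equal(cs$ssb_juice, 1)
  expect_equal(cs$fv_excl_juice, 1)
  expect_equal(cs$total_freq, 2)

  # potatoes never count toward vegetables but do count toward total
  cs <- component_servings(make_responses("boiled_potatoes", "once a day"))
  expect_equal(cs$vegetables, 0)
  expect_equal(cs$total_freq, 1)

  # alcohol excluded from total frequency
  cs <- component_servings(make_responses(c("beer", "apple"),
                                          c("every day", "every day"),
                                          role = "adult"),
                           dialect = adult_dialect())
  expect_equal(cs$total_freq, 1)

  # salad configurable in the vegetable component
  rec <- make_responses("green_salad", "once a day")
  expect_equal(component_servings(rec)$vegetables, 1)
  expect_equal(component_servings(rec, include_salad = FALSE)$vegetables, 0)
  expect_error(component_servings(rec[0, ]), "no response records")
})

test_that("component scores interpolate linearly and clamp to [0, 10]", {
  std <- default_standards()
  veg <- std[std$component == "vegetables", ]
  ssb <- std[std$component == "ssb_juice", ]
  expect_equal(score_component(0, veg), 0)
  expect_equal(score_component(2.5, veg), 5)
  expect_equal(score_component(5, veg), 10)
  expect_equal(score_component(9, veg), 10)   # clamped
  expect_equal(score_component(0, ssb), 10)   # reverse component
  expect_equal(score_component(0.5, ssb), 5)
  expect_equal(score_component(3, ssb), 0)
  expect_error(score_component(-1, veg), "non-negative")
  expect_error(score_component(1, list(zero_score_servings = 1,
                                       full_score_servings = 1)),
               "degenerate")
})

test_that("index invariants hold at the boundary intakes", {
  std <- default_standards()
  full <- tibble::tibble(
    vegetables = 5, fruit_excl_juice = 4, whole_grains = 1.5,
    nuts_legumes = 1, ssb_juice = 0, red_processed_meat = 0,
    fv_excl_juice = 9, healthy_freq = 11.5, total_freq = 11.5)
  idx <- compute_indices(full, std)
  expect_equal(idx$modified_ahei_total, 60)
  expect_equal(idx$healthy_foods_score, 40)
  expect_equal(idx$fv_score, 20)

  zero <- tibble::tibble(
    vegetables = 0, fruit_excl_juice = 0, whole_grains = 0,
    nuts_legumes = 0, ssb_juice = 0, red_processed_meat = 0,
    fv_excl_juice = 0, healthy_freq = 0, total_freq = 0)
  idx0 <- compute_indices(zero, std)
  expect_equal(idx0$modified_ahei_total, 20)  # two reverse components at 10
  expect_equal(idx0$healthy_foods_score, 0)
  expect_true(is.na(idx0$ratio_healthy_total))  # 0/0 is missing, not 0

  quarter <- zero
  quarter$healthy_freq <- 1
  quarter$total_freq <- 4
  expect_equal(compute_indices(quarter, std)$ratio_healthy_total, 0.25)
})

test_that("scoring matches an independent brute-force oracle", {
  set.seed(101)
  reg <- default_registry()
  d <- child_dialect()
  for (i in 1:30) {
    rec <- random_child_responses(reg)
    inc_salad <- i %% 2 == 0
    cs <- component_servings(rec, reg, d, include_salad = inc_salad)
    oracle <- oracle_components(rec, reg, d, include_salad = inc_salad)
    for (nm in names(oracle)) {
      expect_equal(cs[[nm]], unname(oracle[[nm]]), info = nm)
    }
    expect_equal(cs$fv_excl_juice, cs$fruit_excl_juice + cs$vegetables)
    expect_lte(cs$healthy_freq, cs$total_freq + 1e-12)
  }
})

test_that("indices are bounded and monotone under added servings", {
  set.seed(202)
  reg <- default_registry()
  for (i in 1:25) {
    rec <- random_child_responses(reg, n_items = 12)
    idx <- compute_indices(component_servings(rec))
    expect_true(idx$modified_ahei_total >= 0 &&
                  idx$modified_ahei_total <= 60)
    expect_true(idx$healthy_foods_score >= 0 &&
                  idx$healthy_foods_score <= 40)
    expect_true(all(c(idx$vegetables_score, idx$fruit_score,
                      idx$whole_grains_score, idx$nuts_legumes_score,
                      idx$ssb_juice_score,
                      idx$red_processed_meat_score) >= 0))

    # add a healthy serving: healthy-side indices cannot decrease
    healthy_item <- setdiff(reg$item_id[reg$healthy], rec$item_id)[1]
    rec_plus <- rbind(rec, make_responses(healthy_item, "once a day"))
    idx_plus <- compute_indices(component_servings(rec_plus))
    expect_gte(idx_plus$healthy_foods_score, idx$healthy_foods_score)
    expect_gte(idx_plus$fv_score, idx$fv_score)
    expect_gte(idx_plus$healthy_freq, idx$healthy_freq)

    # add an SSB serving: the AHEI total cannot increase
    ssb_item <- setdiff(reg$item_id[reg$ahei_component == "ssb_juice"],
                        rec$item_id)[1]
    if (!is.na(ssb_item)) {
      rec_ssb <- rbind(rec, make_responses(ssb_item, "once a day"))
      idx_ssb <- compute_indices(component_servings(rec_ssb))
      expect_lte(idx_ssb$modified_ahei_total, idx$modified_ahei_total)
    }
  }
})

test_that("score_diets scores whole tables keyed by subject and timepoint", {
  tbl <- rbind(
    make_responses(c("apple", "soda"), c("once a day", "never"),
                   subject_id = "S1"),
    make_responses(c("apple", "soda"), c("never", "once a day"),
                   subject_id = "S1", timepoint = "followup"),
    make_responses(c("squash", "beer"), c("every day", "every day"),
                   subject_id = "A1", role = "adult"))
  out <- score_diets(tbl)
  expect_equal(nrow(out), 3)
  s1b <- out[out$subject_id == "S1" & out$timepoint == "baseline", ]
  expect_equal(s1b$fruit_excl_juice, 1)
  a1 <- out[out$subject_id == "A1", ]
  expect_equal(a1$total_freq, 1)  # beer excluded
  expect_equal(a1$vegetables, 1)

  bad <- make_responses("apple", "not a label")
  expect_error(score_diets(bad), "failed validation")
})
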