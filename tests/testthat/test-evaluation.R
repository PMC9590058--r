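test_that("percent and fold errors follow their defining formulas", {
  expect_equal(percent_error(560, 250), 124)
  expect_equal(percent_error(100, 100), 0)
  expect_equal(percent_error(70, 100), -30)
  expect_equal(fold_error(560, 250), 2.24)
  expect_equal(fold_error(130, 100), 1.3)
  expect_equal(fold_error(5, 5), 1)
  expect_error(percent_error(10, 0), class = "peddose_invalid_input")
  expect_error(fold_error(-1, 10), class = "peddose_invalid_input")
})

test_that("fold and percent error are algebraically linked", {
  set.seed(21)
  p <- runif(200, 1, 1000)
  o <- runif(200, 1, 1000)
  expect_equal(fold_error(p, o), 1 + percent_error(p, o) / 100, tolerance = 1e-12)
})

test_that("fold error is invariant to the comparison basis", {
  set.seed(22)
  perkg_pred <- runif(100, 1, 500)
  perkg_obs <- runif(100, 1, 500)
  w <- runif(100, 1, 60)
  expect_equal(
    fold_error(perkg_pred, perkg_obs),
    fold_error(perkg_pred * w, perkg_obs * w),
    tolerance = 1e-12
  )
})

test_that("classification bands have inclusive narrow boundaries", {
  f <- classify_fold(1.4)
  expect_true(f$within_wide)
  expect_false(f$within_narrow)
  expect_true(f$over)
  expect_false(f$under)

  f1 <- classify_fold(1.0)
  expect_true(f1$within_wide && f1$within_narrow)
  expect_false(f1$over || f1$under)

  # 0.7 and 1.3 belong to the narrow band, not to under/over
  edges <- classify_fold(c(0.7, 1.3))
  expect_true(all(edges$within_narrow))
  expect_false(any(edges$over | edges$under))

  expect_error(classify_fold(0), class = "peddose_invalid_input")
})

test_that("narrow/over/under partition and wide nests narrow on random folds", {
  set.seed(23)
  folds <- exp(runif(10000, log(0.1), log(10)))
  flags <- classify_fold(folds)
  expect_true(all(flags$within_narrow + flags$over + flags$under == 1L))
  expect_true(all(!flags$within_narrow | flags$within_wide))
  counts <- c(
    wide = sum(flags$within_wide), narrow = sum(flags$within_narrow),
    over = sum(flags$over), under = sum(flags$under)
  )
  expect_identical(counts, brute_count_categories(folds))
})

test_that("evaluate_cohort matches hand-computed per-kg errors", {
  res <- evaluate_cohort(manual_cohort())
  # 20 kg child on the adult 10 mg/kg label: 40% over-prediction
  expect_equal(res$percent_error[1], 40)
  expect_true(res$over[1])
  # 35 kg child: (65/100) * (70/35) = 1.3 exactly, inside the narrow band
  expect_equal(res$fold_error[2], 1.3)
  expect_equal(res$percent_error[2], 30)
  expect_true(res$within_narrow[2])
  expect_false(res$over[2])
  # 2 kg neonate given 250 mg/kg vs 400 mg/kg adult regimen: 124% error
  expect_equal(res$percent_error[3], 124)
  expect_equal(res$fold_error[3], 2.24)
  expect_identical(res$stratum, c("lt30", "ge30", "neonate"))
})

test_that("a 70 kg child receives exactly the adult dose (zero error)", {
  cohort <- manual_cohort()[1, ]
  cohort$weight_kg <- 70
  res <- suppressWarnings(evaluate_cohort(cohort))
  expect_equal(res$percent_error, 0)
  expect_equal(res$fold_error, 1)
})

test_that("cl_based rows reconstruct the observed dose from clearances", {
  cohort <- manual_cohort()[1, ]
  cohort$reference_type <- "cl_based"
  cohort$observed_dose <- NA_real_
  cohort$cl_child <- 8
  cohort$cl_adult <- 20
  cohort$cl_basis <- "absolute"
  cohort$cl_unit <- "mL/h"
  res <- evaluate_cohort(cohort)
  # adult 10 mg/kg at 70 kg -> per-kg cl dose = 10 * (8/20); child 20 kg
  expect_equal(res$observed_per_kg, 10 * 8 / 20)
  # prediction: (2*20)% of 700 mg = 280 mg -> 14 mg/kg
  expect_equal(res$predicted_per_kg, 14)
  expect_equal(res$fold_error, 14 / 4)

  cohort$cl_child <- NA_real_
  expect_error(evaluate_cohort(cohort), "drug 'a'",
    class = "peddose_missing_field"
  )
})

test_that("summaries equal a brute-force recount on a synthetic cohort", {
  cohort <- generate_cohort(synthetic_config(seed = 99, obs_per_drug = 3))
  res <- evaluate_cohort(cohort)
  summ <- summarize_predictions(res)
  expect_true(nrow(summ) >= 1)
  for (i in seq_len(nrow(summ))) {
    sub <- res[
      res$class == summ$class[i] & res$stratum == summ$stratum[i] &
        res$reference_type == summ$reference_type[i],
    ]
    counts <- brute_count_categories(sub$fold_error)
    expect_identical(as.integer(summ$n[i]), nrow(sub))
    expect_identical(as.integer(summ$wide_n[i]), unname(counts["wide"]))
    expect_identical(as.integer(summ$narrow_n[i]), unname(counts["narrow"]))
    expect_identical(as.integer(summ$over_n[i]), unname(counts["over"]))
    expect_identical(as.integer(summ$under_n[i]), unname(counts["under"]))
    expect_equal(
      summ$narrow_n[i] + summ$over_n[i] + summ$under_n[i],
      summ$n[i]
    )
    expect_true(summ$wide_n[i] >= summ$narrow_n[i])
  }
})

test_that("published stratified percentages are recovered from raw counts", {
  # 31 observations: 11 narrow, 17 over, 3 under, 27 within the wide band
  folds <- c(
    rep(1.0, 11),      # narrow (also wide)
    rep(1.4, 13),      # over, within wide
    rep(1.6, 4),       # over, outside wide
    rep(0.6, 3)        # under, within wide
  )
  cohort <- manual_cohort()[rep(1, 31), ]
  cohort$weight_kg <- 20
  # predicted per-kg at 20 kg under the 10 mg/kg adult label is 14;
  # choose observed doses so the fold errors land exactly on `folds`
  cohort$observed_dose <- 14 / folds
  res <- evaluate_cohort(cohort)
  expect_equal(res$fold_error, folds, tolerance = 1e-12)
  summ <- summarize_predictions(res)
  expect_equal(summ$n, 31L)
  expect_equal(summ$wide_n, 27L)
  expect_equal(summ$wide_pct, 87.1)
  expect_equal(summ$narrow_pct, 35.5)
  expect_equal(summ$over_pct, 54.8)
  expect_equal(summ$under_pct, 9.7)
})

test_that("a single observation yields only 0 or 100 percents", {
  res <- evaluate_cohort(manual_cohort()[1, ])
  summ <- summarize_predictions(res)
  pcts <- unlist(summ[, c("wide_pct", "narrow_pct", "over_pct", "under_pct")])
  expect_true(all(pcts %in% c(0, 100)))
})

test_that("empty input summarises to a marked zero-row table, not an error", {
  res <- evaluate_cohort(manual_cohort()[0, ])
  expect_equal(nrow(res), 0)
  summ <- summarize_predictions(res)
  expect_equal(nrow(summ), 0)
  expect_true(isTRUE(attr(summ, "empty_cohort")))
  expect_match(summary_markdown(summ), "empty cohort")
})

test_that("markdown report carries the four category labels and NA cells", {
  res <- evaluate_cohort(manual_cohort())
  md <- summary_markdown(summarize_predictions(res))
  txt <- paste(md, collapse = "\n")
  expect_match(txt, "0.5\u20131.5-fold", fixed = TRUE)
  expect_match(txt, "\u226430% (\u22650.7\u2013\u22641.3)", fixed = TRUE)
  expect_match(txt, "\u2265130% (>1.3-fold)", fixed = TRUE)
  expect_match(txt, "\u226470% (\u22640.7-fold)", fixed = TRUE)
  # the monoclonal class has no neonate stratum: rendered as NA, not dropped
  expect_match(txt, "NA", fixed = TRUE)
})

test_that("percent formatting rounds half away from zero", {
  expect_equal(round_half_out(87.05, 1), 87.1)
  expect_equal(round_half_out(-87.05, 1), -87.1)
  expect_equal(round_half_out(0.5), 1)
  expect_equal(round_half_out(-0.5), -1)
  expect_equal(round_half_out(12.449, 1), 12.4)
})
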