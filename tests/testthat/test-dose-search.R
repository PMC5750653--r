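test_that("the titration grid has the stated segments and refinement", {
  g <- dose_grid()
  expect_equal(min(g), 10)
  expect_equal(max(g), 210)
  expect_true(all(seq(10, 100, by = 2) %in% g))
  expect_true(all(seq(100, 210, by = 10) %in% g))
  expect_true(20.7 %in% g && 25.6 %in% g) # 0.1 resolution inside [20, 30]
  expect_false(any(g > 30 & g < 32))      # but not outside it
  expect_true(!is.unsorted(g) && !anyDuplicated(g))
  expect_error(dose_grid(coarse_step = -1), "positive")
})

test_that("with BSV off the optimum inverts the closed-form trough", {
  # identical typical subjects: the optimal dose is the closed-form dose
  # giving a steady-state trough of exactly 1, rounded up to the grid
  ht <- 176
  bmi <- 27
  tbw <- bmi * (ht / 100)^2
  pop <- cbind(data.frame(patient_id = sprintf("p%d", 1:5), group = "normal",
                          height_cm = ht, bmi = bmi),
               weight_metrics(rep(ht, 5), rep(tbw, 5), rep(bmi, 5)))
  pk0 <- typical_pk_parameters(pk_model_spec(), pop$lbw_kg)
  unit_ss <- ss_trough_q48h_oracle(pk0[1, ], 1, baseline = 0)
  d_exact <- 0.5 / (tbw * unit_ss)
  g <- dose_grid()
  expected <- g[which(g >= d_exact)[1]]
  opt <- find_optimal_dose(pop, pk0, metric = "TBW", baseline = 0.5)
  expect_equal(opt$optimal_dose_per_kg, expected)
  expect_true(opt$achieved)
  expect_equal(opt$safe_ratio_at_optimum, 1)
})

test_that("a zero criterion returns the grid minimum", {
  ch <- make_test_cohort(n = 10, seed = 12)
  opt <- find_optimal_dose(ch$pop, ch$pk, criterion = 0)
  expect_equal(opt$optimal_dose_per_kg, 10)
})

test_that("grid scan and binary search return identical optima", {
  for (k in 1:20) {
    ch <- make_test_cohort(n = 30, seed = 400 + k)
    metric <- sample(c("TBW", "LBW", "IBW", "ABW25", "ABW40"), 1)
    baseline <- sample(c(0.5, 0), 1)
    scan <- find_optimal_dose(ch$pop, ch$pk, metric = metric,
                              baseline = baseline, method = "scan")
    bis <- find_optimal_dose(ch$pop, ch$pk, metric = metric,
                             baseline = baseline, method = "bisect")
    expect_identical(scan$optimal_dose_per_kg, bis$optimal_dose_per_kg)
    expect_identical(scan$achieved, bis$achieved)
  }
})

test_that("the exact titration fast path agrees with brute-force evaluation", {
  ch <- make_test_cohort(n = 40, seed = 17)
  opt <- find_optimal_dose(ch$pop, ch$pk, metric = "IBW", baseline = 0.5)
  # the safe ratio at (and just below) the optimum, recomputed from full
  # concentration profiles
  at <- evaluate_cohort(ch$pop, ch$pk,
                        dosing_regimen("q48h", "IBW",
                                       opt$optimal_dose_per_kg))
  expect_equal(at$safe_ratio, opt$safe_ratio_at_optimum)
  expect_gte(at$safe_ratio, 0.95)
  g <- dose_grid()
  below <- g[which(g == opt$optimal_dose_per_kg) - 1]
  prev <- evaluate_cohort(ch$pop, ch$pk, dosing_regimen("q48h", "IBW", below))
  expect_lt(prev$safe_ratio, 0.95)
})

test_that("safety is monotone in dose and in criterion relaxation", {
  ch <- make_test_cohort(n = 50, seed = 23)
  opt <- find_optimal_dose(ch$pop, ch$pk, metric = "TBW", baseline = 0.5)
  expect_true(all(diff(opt$curve$safe_ratio) >= 0))
  # per-subject time below threshold shrinks as dose grows
  h <- vapply(c(10, 20, 40), function(d)
    evaluate_cohort(ch$pop, ch$pk,
                    dosing_regimen("q48h", "TBW", d))$per_patient$hours_below_1,
    numeric(nrow(ch$pop)))
  expect_true(all(h[, 2] <= h[, 1] & h[, 3] <= h[, 2]))
  # relaxing the criterion never raises the optimum
  opt90 <- find_optimal_dose(ch$pop, ch$pk, metric = "TBW", baseline = 0.5,
                             criterion = 0.90)
  expect_lte(opt90$optimal_dose_per_kg, opt$optimal_dose_per_kg)
  # removing the endogenous baseline never lowers it
  opt_b0 <- find_optimal_dose(ch$pop, ch$pk, metric = "TBW", baseline = 0)
  expect_gte(opt_b0$optimal_dose_per_kg, opt$optimal_dose_per_kg)
})

test_that("an unreachable criterion yields an explicit non-achievable result", {
  ch <- make_test_cohort(n = 10, seed = 29)
  tiny <- dose_grid(coarse_range = c(0.01, 0.05), coarse_step = 0.01,
                    wide_range = c(0.05, 0.1), wide_step = 0.01,
                    fine_step = NULL)
  opt <- find_optimal_dose(ch$pop, ch$pk, baseline = 0, grid = tiny)
  expect_false(opt$achieved)
  expect_true(is.na(opt$optimal_dose_per_kg))
  expect_lt(opt$safe_ratio_at_optimum, 0.95)
})

test_that("Friday escalation compensates the weekend gap", {
  ch <- make_test_cohort(n = 40, seed = 31)
  base <- find_optimal_dose(ch$pop, ch$pk, metric = "TBW",
                            baseline = 0.5)$optimal_dose_per_kg
  fri <- find_optimal_friday_dose(ch$pop, ch$pk, metric = "TBW",
                                  baseline = 0.5, base_dose_per_kg = base)
  expect_true(fri$achieved)
  expect_gt(fri$optimal_dose_per_kg, base)
  # brute-force check at the optimum and one grid step below
  at <- evaluate_cohort(ch$pop, ch$pk,
                        dosing_regimen("mwf", "TBW", base,
                                       friday_dose_per_kg = fri$optimal_dose_per_kg))
  expect_gte(at$safe_ratio, 0.95)
  g <- dose_grid()
  below <- g[which(g == fri$optimal_dose_per_kg) - 1]
  prev <- evaluate_cohort(ch$pop, ch$pk,
                          dosing_regimen("mwf", "TBW", base,
                                         friday_dose_per_kg = below))
  expect_lt(prev$safe_ratio, 0.95)

  # scan and bisect agree for the Friday search too
  fri_b <- find_optimal_friday_dose(ch$pop, ch$pk, metric = "TBW",
                                    baseline = 0.5, base_dose_per_kg = base,
                                    method = "bisect")
  expect_identical(fri$optimal_dose_per_kg, fri_b$optimal_dose_per_kg)
})

test_that("with BSV off the Friday optimum inverts the weekend trough", {
  ht <- 176
  bmi <- 27
  tbw <- bmi * (ht / 100)^2
  pop <- cbind(data.frame(patient_id = sprintf("p%d", 1:3), group = "normal",
                          height_cm = ht, bmi = bmi),
               weight_metrics(rep(ht, 3), rep(tbw, 3), rep(bmi, 3)))
  pk0 <- typical_pk_parameters(pk_model_spec(), pop$lbw_kg)
  base <- 20
  fri <- find_optimal_friday_dose(pop, pk0, metric = "TBW", baseline = 0.5,
                                  base_dose_per_kg = base)
  # independent check: smallest grid Friday dose whose simulated weekly
  # trough reaches 1, found by brute force over the grid
  g <- dose_grid()
  ok <- vapply(g, function(f) {
    analysis_week_outcome(pk0[1, ],
                          dosing_regimen("mwf", "TBW", base,
                                         friday_dose_per_kg = f),
                          tbw)$cmin >= 1
  }, logical(1))
  expect_equal(fri$optimal_dose_per_kg, g[which(ok)[1]])
})
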