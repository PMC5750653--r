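small_config <- function(...) {
  study_config(n_per_group = 40, seed = 5,
               metrics = c("TBW", "IBW"),
               schedules = "q48h", baselines = 0.5,
               groups = c("normal", "overweight_obese"), ...)
}

test_that("a degenerate configuration yields a one-row report", {
  cfg <- study_config(n_per_group = 20, seed = 2, metrics = "TBW",
                      schedules = "q48h", baselines = 0.5, groups = "normal")
  st <- run_full_study(cfg)
  expect_equal(nrow(st$results), 1)
  expect_true(st$results$achieved)
  expect_equal(st$results$consumption_diff_vs_tbw, 0)
  expect_output(print(st), "FVIII prophylaxis dosing study")
})

test_that("the study report is seed-reproducible", {
  s1 <- run_full_study(small_config())
  s2 <- run_full_study(small_config())
  expect_identical(s1$results, s2$results)
  expect_identical(as.data.frame(s1$population), as.data.frame(s2$population))
})

test_that("reported consumption equals dose x mean metric mass x doses/week", {
  st <- run_full_study(small_config())
  for (i in seq_len(nrow(st$results))) {
    row <- st$results[i, ]
    idx <- st$population$group == row$group
    mcol <- c(TBW = "tbw_kg", IBW = "ibw_kg")[[row$metric]]
    recomputed <- 3.5 * row$optimal_dose_per_kg *
      mean(st$population[[mcol]][idx])
    expect_equal(row$mean_weekly_consumption, recomputed)
  }
})

test_that("mwf cells reuse the q48h optimum as the Monday/Wednesday dose", {
  cfg <- study_config(n_per_group = 40, seed = 9, metrics = "TBW",
                      schedules = c("q48h", "mwf"), baselines = 0.5,
                      groups = "normal", criterion_mwf = 0.90)
  st <- run_full_study(cfg)
  q48 <- st$results[st$results$schedule == "q48h", ]
  mwf <- st$results[st$results$schedule == "mwf", ]
  expect_equal(mwf$base_dose_per_kg, q48$optimal_dose_per_kg)
  expect_equal(mwf$criterion, 0.90)
  if (mwf$achieved)
    expect_equal(mwf$mean_weekly_consumption,
                 mean((2 * mwf$base_dose_per_kg + mwf$optimal_dose_per_kg) *
                      st$population$tbw_kg[st$population$group == "normal"]))
})

test_that("configs round-trip through YAML and reject unknown keys", {
  cfg <- study_config(n_per_group = 12, seed = 3,
                      pk = list(cl_typical = 2.0),
                      bmi_high_range = c(29.6, 35.0))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  back <- load_study_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  expect_equal(attr(back, "pk_spec")$cl_typical, 2.0)

  # empty file: full defaults
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(unclass(load_study_config(empty)), unclass(study_config()))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_per_grp: 10", bad)
  expect_error(load_study_config(bad), "n_per_grp")
  writeLines("pk:\n  clearance: 2", bad)
  expect_error(load_study_config(bad), "clearance")
})

test_that("the report writer emits tables, cohort CSV and manifest", {
  st <- run_full_study(small_config())
  dir <- withr::local_tempdir()
  paths <- write_study_report(st, dir)
  expect_true(all(file.exists(paths)))
  res <- utils::read.csv(file.path(dir, "results.csv"))
  expect_true("consumption_diff_vs_tbw" %in% names(res))
  # difference column is metric consumption minus TBW consumption
  for (g in unique(res$group)) {
    sub <- res[res$group == g, ]
    tbw <- sub$mean_weekly_consumption[sub$metric == "TBW"]
    expect_equal(sub$consumption_diff_vs_tbw,
                 sub$mean_weekly_consumption - tbw)
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 5)
  expect_match(man$config_md5, "^[0-9a-f]{32}$")

  # rerunning the same seed reproduces the tables byte-identically
  dir2 <- withr::local_tempdir()
  write_study_report(run_full_study(small_config()), dir2)
  expect_identical(readLines(file.path(dir, "results.csv")),
                   readLines(file.path(dir2, "results.csv")))
})
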