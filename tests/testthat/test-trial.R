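test_that("trial schedules follow the daily meal plan", {
  s <- build_schedule("adult", 1)
  expect_equal(s$cho_true, c(30, 45, 30, 45, 15))
  expect_equal(s$t_min, c(0, 240, 480, 720, 960))
  expect_equal(s$clock, c("08:00", "12:00", "16:00", "20:00", "00:00"))
  s90 <- build_schedule("child", 90)
  expect_equal(nrow(s90), 450)
  expect_equal(sum(s90$cho_true), 90 * 135)
  adol <- build_schedule("adolescent", 1)
  expect_equal(sum(adol$cho_true), 195)
  expect_error(build_schedule("adult", 0), "positive integer")
})

test_that("the control experiment E0 is always part of a configuration", {
  cfg <- trial_config(days = 2, experiments = c("E8", "E9"))
  expect_true("E0" %in% cfg$experiments)
  expect_error(trial_config(experiments = c("E0", "EX")), "unknown")
})

test_that("a trial cell logs every meal and doses the control exactly", {
  pat <- load_reference_roster()[1, ]  # Adult#1
  cal <- cached_calibration(pat$icr, pat$isf)
  cfg <- small_config()
  cell <- run_experiment(pat, "E0", cfg, params = cal, keep_trace = TRUE)
  expect_equal(nrow(cell$meals), cfg$days * 5)
  expect_true(all(cell$meals$delta_cho == 0))
  expect_equal(cell$meals$cho_estimated, cell$meals$cho_true)
  expect_equal(nrow(cell$trace), cfg$days * 288)
  expect_gte(cell$outcome$tir, 99)
  # meal-log invariants under error injection
  e8 <- run_experiment(pat, "E8", cfg, params = cal)
  expect_equal(e8$meals$cho_estimated,
               pmax(0, e8$meals$cho_true - e8$meals$delta_cho))
  th <- therapy_params(pat$icr, pat$isf)
  expect_equal(e8$meals$bolus,
               compute_bolus(e8$meals$cho_estimated,
                             e8$meals$g_preprandial, th))
  # identical seed derivation: re-running a cell reproduces it exactly
  e8b <- run_experiment(pat, "E8", cfg, params = cal)
  expect_identical(e8, e8b)
})

test_that("error directions push glucose the expected way", {
  pat <- load_reference_roster()[16, ]  # Adolescent#5, tightest safe limit
  cal <- cached_calibration(pat$icr, pat$isf)
  cfg <- small_config()
  e0 <- run_experiment(pat, "E0", cfg, params = cal)$outcome
  e8 <- run_experiment(pat, "E8", cfg, params = cal)$outcome
  e9 <- run_experiment(pat, "E9", cfg, params = cal)$outcome
  # underestimation beyond the limit: hyperglycemia dominates
  expect_gt(e8$tar - e0$tar, e8$tbr - e0$tbr)
  # overestimation beyond the limit: hypoglycemia dominates
  expect_gt(e9$tbr - e0$tbr, e9$tar - e0$tar)
})

test_that("a small trial assembles outcomes, strata and comparisons", {
  cfg <- small_config()
  fit <- run_trial(cfg, roster = tiny_roster(), keep_meal_logs = TRUE)
  expect_s3_class(fit, "cc_trial")
  expect_equal(nrow(fit$outcomes), 3 * 4)
  expect_equal(nrow(fit$meal_logs), 3 * 4 * cfg$days * 5)
  # comparisons: 3 non-control experiments x 5 metrics x 2 strata
  expect_equal(nrow(fit$comparisons), 3 * 5 * 2)
  expect_true(all(fit$comparisons$ci_low <= fit$comparisons$mean_diff +
                    1e-12))
  expect_true(all(fit$comparisons$mean_diff <= fit$comparisons$ci_high +
                    1e-12))
  expect_output(print(fit), "3 patients x 4 experiments")
  expect_output(print(summary(fit)), "mean difference vs E0")
})

test_that("a control-only configuration yields metrics but no comparisons", {
  cfg <- trial_config(days = 2, experiments = "E0", master_seed = 3)
  fit <- run_trial(cfg, roster = tiny_roster()[1, , drop = FALSE])
  expect_equal(nrow(fit$outcomes), 1)
  expect_equal(nrow(fit$comparisons), 0)
})

test_that("identical master seeds reproduce output files byte for byte", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_trial(cfg, roster = tiny_roster(), out_dir = d1)
  run_trial(cfg, roster = tiny_roster(), out_dir = d2)
  for (f in c("metrics.csv", "comparisons.csv", "roster.csv",
              "manifest.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
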