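test_that("basal-only simulation holds the fasting equilibrium", {
  p <- metabolic_params()
  basal <- p$i_b * p$i_clear * 60
  tr <- simulate_response(p, basal, horizon = 1440)
  expect_equal(nrow(tr), 288)          # 5-min CGM grid, 288 samples/day
  expect_identical(unique(diff(tr$t_min)), 5)
  expect_true(all(abs(tr$glucose_mgdl - p$g_b) <= 1))
})

test_that("absorbed meal mass equals bioavailability times meal size", {
  p <- metabolic_params()
  basal <- p$i_b * p$i_clear * 60
  tr <- simulate_response(p, basal, meals = data.frame(time = 0, grams = 60),
                          horizon = 900, check_positive = FALSE,
                          full_state = TRUE)
  ra <- tr$ra_mg_min
  absorbed <- sum((ra[-1] + ra[-length(ra)]) / 2 * 5)  # trapezoid, mg
  expect_equal(absorbed, p$bioavail * 60 * 1000,
               tolerance = 0.01)
})

test_that("a larger bolus lowers glucose pointwise, never raises it", {
  p <- cached_calibration(15.9, 42.2)
  basal <- p$i_b * p$i_clear * 60
  run <- function(units)
    simulate_response(p, basal, meals = data.frame(time = 0, grams = 45),
                      boluses = data.frame(time = 0, units = units),
                      horizon = 600, check_positive = FALSE)$glucose_mgdl
  g1 <- run(1); g2 <- run(2); g4 <- run(4)
  expect_true(all(g2 <= g1 + 1e-9))
  expect_true(all(g4 <= g2 + 1e-9))
})

test_that("calibration reproduces the assigned ISF and meal recovery", {
  p <- cached_calibration(15.9, 42.2)
  isf_hat <- measure_isf(p)
  expect_lt(abs(isf_hat - 42.2) / 42.2, 0.01)
  expect_lt(abs(measure_meal_recovery(p, 15.9) - p$g_b), 2)
  # correctly dosed 45 g meal is back near target 2-3 h after eating
  basal <- p$i_b * p$i_clear * 60
  tr <- simulate_response(p, basal, meals = data.frame(time = 0, grams = 45),
                          boluses = data.frame(time = 0, units = 45 / 15.9),
                          horizon = 480)
  win <- tr$glucose_mgdl[tr$t_min >= 120 & tr$t_min <= 180]
  expect_true(all(abs(win - 100) <= 15))
})

test_that("calibration is deterministic and its gain tracks the ISF", {
  a <- calibrate_patient(therapy_params(17.6, 57.1))
  b <- calibrate_patient(therapy_params(17.6, 57.1))
  expect_identical(a, b)
  dbl <- cached_calibration(17.6, 2 * 57.1)
  base <- cached_calibration(17.6, 57.1)
  expect_gt(dbl$si, base$si)
  # additive insulin action: gain scales linearly with the target ISF
  expect_equal(dbl$si / base$si, 2, tolerance = 0.05)
})

test_that("steady-state basal holds fasting glucose and detects degeneracy", {
  p <- metabolic_params()
  b <- steady_state_basal(p)
  tr <- simulate_response(p, b, horizon = 48 * 60)
  expect_true(all(abs(tr$glucose_mgdl - p$g_b) <= 2))
  # doubling insulin clearance requires more basal insulin
  p2 <- metabolic_params(i_clear = 2 * p$i_clear)
  expect_gt(steady_state_basal(p2), b)
  # vanishing sensitivity: glucose does not respond to basal -> no bracket
  expect_error(steady_state_basal(metabolic_params(si = 1e-8)),
               "no bracketing basal")
})

test_that("bad inputs and uncalibrated overdoses fail loudly", {
  p <- metabolic_params()
  expect_error(simulate_response(p, 1, horizon = 123), "multiple of 5")
  expect_error(simulate_response(p, 1, meals = data.frame(time = 7, grams = 10),
                                 horizon = 100), "5-min grid")
  expect_error(simulate_response(p, 1,
                                 boluses = data.frame(time = 0, units = 500),
                                 horizon = 600), "non-positive")
})
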