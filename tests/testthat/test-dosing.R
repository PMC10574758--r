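test_that("safe CC-error limit reproduces known therapy configurations", {
  thr <- glucose_thresholds()
  # ratio back-computed from a roster subject: icr/isf = 13.11/30
  expect_equal(compute_delta_cho_max(therapy_params(13.11, 30), thr), 13.11)
  # adult population means
  expect_equal(compute_delta_cho_max(therapy_params(15.9, 42.2), thr),
               30 * 15.9 / 42.2)
  # unit icr/isf ratio with asymmetric thresholds: headroom 55 both sides
  expect_equal(compute_delta_cho_max(therapy_params(8, 8),
                                     glucose_thresholds(70, 125, 180)), 55)
})

test_that("safe limit is homogeneous in ICR and inversely in ISF", {
  thr <- glucose_thresholds()
  base <- compute_delta_cho_max(therapy_params(12, 40), thr)
  for (k in c(0.5, 2, 10)) {
    expect_equal(compute_delta_cho_max(therapy_params(12 * k, 40), thr),
                 k * base)
    expect_equal(compute_delta_cho_max(therapy_params(12, 40 * k), thr),
                 base / k)
  }
  # standard thresholds: closed form 30 * icr / isf to machine precision
  for (icr in c(5, 15.9, 26.5)) for (isf in c(30, 42.2, 117.8))
    expect_equal(compute_delta_cho_max(therapy_params(icr, isf), thr),
                 30 * icr / isf, tolerance = 1e-15)
})

test_that("invalid therapy or threshold inputs are rejected", {
  expect_error(therapy_params(-1, 40), "positive")
  expect_error(therapy_params(15, 0), "positive")
  expect_error(glucose_thresholds(100, 70, 180), "g_low < g_target")
  expect_error(glucose_thresholds(-70, 100, 180), "positive")
  expect_error(compute_delta_cho_max(list(icr = 1, isf = 1)), "therapy")
})

test_that("bolus calculator covers carbs, corrects glucose, clamps at zero", {
  th <- therapy_params(15, 50)
  expect_equal(compute_bolus(45, 100, th), 3.0)  # correction vanishes at target
  expect_equal(compute_bolus(30, 180, therapy_params(15, 40)), 4.0)
  # raw dose of -1 U clamps to zero
  expect_equal(compute_bolus(0, 70, therapy_params(15, 30)), 0.0)
  expect_error(compute_bolus(-5, 100, th), "cho_estimated")
  expect_error(compute_bolus(45, 100, th, iob = -1), "iob")
})

test_that("bolus is monotone in carbs and glucose, antitone in IOB", {
  th <- therapy_params(12, 35)
  cho <- seq(0, 120, by = 5)
  expect_true(all(diff(compute_bolus(cho, 140, th)) >= 0))
  g <- seq(40, 400, by = 10)
  expect_true(all(diff(compute_bolus(50, g, th)) >= 0))
  iob <- seq(0, 6, by = 0.5)
  b <- vapply(iob, function(x) compute_bolus(50, 140, th, iob = x), 0)
  expect_true(all(diff(b) <= 0))
})

test_that("carb estimate applies the error with a zero-gram floor", {
  expect_equal(estimate_cho(45, 0), 45)       # error-free control
  expect_equal(estimate_cho(30, 13.11), 16.89)
  expect_equal(estimate_cho(15, 20), 0)       # clamped
  # overestimation raises the estimate
  expect_gt(estimate_cho(30, -5), 30)
  # round trip whenever the floor is not hit
  set.seed(42)
  x <- runif(50, 0, 100)
  d <- runif(50, -50, 50)
  ok <- x - d >= 0
  expect_equal(estimate_cho(x, d)[ok] + d[ok], x[ok])
})
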