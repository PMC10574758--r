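test_that("control-arm exclusion retains and stratifies subjects", {
  rec <- data.frame(id = c("a", "b", "c"), tir = c(100, 95, 85))
  s <- exclude_subjects(rec, 90)
  expect_identical(s$retained, c("a", "b"))
  expect_identical(s$excluded, "c")
  expect_identical(s$tir100, "a")
  expect_identical(s$tir90, c("a", "b"))
  all100 <- data.frame(id = c("a", "b"), tir = c(100, 100))
  s2 <- exclude_subjects(all100)
  expect_identical(s2$tir100, s2$tir90)
  expect_error(exclude_subjects(data.frame(id = c("a", "a"),
                                           tir = c(99, 98))),
               "one control record")
})

test_that("normality gate holds its level and detects skew", {
  flags_norm <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    shapiro_wilk_gate(rnorm(50))$normal
  }, logical(1))
  expect_gte(mean(flags_norm), 0.9)
  flags_exp <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    shapiro_wilk_gate(rexp(50))$normal
  }, logical(1))
  expect_lte(mean(flags_exp), 0.1)
  expect_error(shapiro_wilk_gate(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk_gate(rep(5, 20)), "degenerate")
})

test_that("degenerate paired samples give exact bootstrap results", {
  x <- c(95, 90, 85, 99)
  same <- bootstrap_paired_diff(x, x, n_resamples = 1000, seed = 1)
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$ci_low, same$ci_high), c(0, 0))
  expect_equal(same$p_value, 1)
  shifted <- bootstrap_paired_diff(x + 3, x, n_resamples = 1000, seed = 1)
  expect_equal(shifted$mean_diff, 3)
  expect_equal(c(shifted$ci_low, shifted$ci_high), c(3, 3))
  expect_error(bootstrap_paired_diff(1, 2), "at least 2")
  expect_error(bootstrap_paired_diff(1:3, 1:4), "equal length")
})

test_that("bootstrap is seed-reproducible and shift-equivariant", {
  set.seed(12)
  ve <- rnorm(20, 95, 3); vc <- rnorm(20, 98, 2)
  a <- bootstrap_paired_diff(ve, vc, n_resamples = 3000, seed = 77)
  b <- bootstrap_paired_diff(ve, vc, n_resamples = 3000, seed = 77)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$mean_diff && a$mean_diff <= a$ci_high)
  cshift <- 4.2
  s <- bootstrap_paired_diff(ve + cshift, vc, n_resamples = 3000, seed = 77)
  expect_equal(s$mean_diff, a$mean_diff + cshift)
  expect_equal(s$ci_low, a$ci_low + cshift, tolerance = 1e-12)
  expect_equal(s$ci_high, a$ci_high + cshift, tolerance = 1e-12)
})

test_that("interval width shrinks with the number of subjects", {
  mean_width <- function(n) {
    mean(vapply(1:20, function(i) {
      set.seed(300 * n + i)
      d <- rnorm(n, 1, 1)
      bt <- bootstrap_paired_diff(d, rep(0, n), n_resamples = 2000,
                                  seed = 500 + i)
      bt$ci_high - bt$ci_low
    }, numeric(1)))
  }
  w <- vapply(c(10, 40, 160), mean_width, numeric(1))
  expect_true(all(diff(w) < 0))
  # rough O(1/sqrt(n)) scaling: quadrupling n about halves the width
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
})
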