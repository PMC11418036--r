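test_that("median quantile polynomial recovers noise-free curves", {
  age <- seq(18, 25, length.out = 120)
  bias <- 2 + 0.5 * age
  fit <- fit_bias_age_curve(age, bias, degree = 4)
  expect_equal(eval_trend(fit, seq(18, 25, by = 0.5)),
               2 + 0.5 * seq(18, 25, by = 0.5), tolerance = 1e-6)
  # symmetric noise around a constant: fitted level near the constant
  set.seed(31)
  age2 <- runif(400, 18, 25)
  bias2 <- 5 + runif(400, -3, 3)
  fit2 <- fit_bias_age_curve(age2, bias2, degree = 4)
  expect_lt(max(abs(eval_trend(fit2, seq(19, 24, by = 0.5)) - 5)), 1)
  expect_error(fit_bias_age_curve(rep(20, 60), rnorm(60)), "degenerate")
})

test_that("degree-0 median quantile fit equals the sample median", {
  set.seed(12)
  b <- rnorm(75, 3, 2)
  fit <- fit_bias_age_curve(runif(75, 18, 25), b, degree = 0)
  expect_identical(eval_trend(fit, 20), median(b))
  expect_identical(eval_trend(fit, 20), median_bias(b, rep(0, 75)))
})

test_that("check loss of the fitted line is near-optimal", {
  # small instance where a fine grid over (intercept, slope) is feasible
  set.seed(7)
  age <- runif(40, 18, 25)
  bias <- 1 + 0.8 * (age - 21) + rt(40, df = 3)
  fit <- fit_bias_age_curve(age, bias, degree = 1)
  loss <- function(f) sum(abs(bias - f(age)))
  fitted_loss <- loss(function(a) eval_trend(fit, a))
  grid <- expand.grid(b0 = seq(-2, 4, by = 0.02),
                      b1 = seq(0.2, 1.4, by = 0.02))
  grid_loss <- min(vapply(seq_len(nrow(grid)), function(i) {
    loss(function(a) grid$b0[i] + grid$b1[i] * (a - 21))
  }, numeric(1)))
  expect_lte(fitted_loss, grid_loss + 1e-6)
})

test_that("evaluation is refused outside the stored age range", {
  age <- seq(18, 25, length.out = 80)
  fit <- fit_bias_age_curve(age, rnorm(80), degree = 2,
                            eval_range = c(19, 24))
  expect_error(eval_trend(fit, 18.5), "refused")
  expect_silent(eval_trend(fit, 19.5))
  expect_error(fit_bias_age_curve(age, rnorm(80), eval_range = c(10, 24)),
               "within")
})

test_that("free-knot P30 spline tracks binned truth and honors contracts", {
  # constant outcome: constant curve
  fit <- fit_p30_age_curve(runif(200, 18, 25), rep(1, 200))
  expect_equal(eval_trend(fit, c(19, 22, 24)), rep(100, 3))
  # piecewise truth: 90% below age 22, 60% above
  set.seed(17)
  n <- 5000
  age <- runif(n, 18, 25)
  p <- ifelse(age < 22, 0.9, 0.6)
  y <- rbinom(n, 1, p)
  fit <- fit_p30_age_curve(age, y)
  expect_equal(length(fit$knots), 3)
  expect_true(all(diff(fit$knots) > 0))
  expect_true(all(fit$knots > 18 & fit$knots < 25))
  away <- c(seq(18.5, 20.8, by = 0.2), seq(23.2, 24.5, by = 0.2))
  truth <- ifelse(away < 22, 90, 60)
  expect_lt(max(abs(eval_trend(fit, away) - truth)), 5)
  # fitted values are clipped to [0, 100]
  g <- seq(fit$eval_age_range[1], fit$eval_age_range[2], length.out = 100)
  expect_true(all(eval_trend(fit, g) <= 100 & eval_trend(fit, g) >= 0))
})

test_that("spline fit is invariant to permuting input rows", {
  set.seed(23)
  age <- runif(600, 18, 25)
  y <- rbinom(600, 1, 0.8)
  f1 <- fit_p30_age_curve(age, y)
  o <- sample(600)
  f2 <- fit_p30_age_curve(age[o], y[o])
  expect_equal(f1$knots, f2$knots)
  g <- seq(18.2, 24.8, by = 0.3)
  expect_equal(eval_trend(f1, g), eval_trend(f2, g), tolerance = 1e-8)
})

test_that("Bland-Altman summaries: limits, modes, shift property", {
  m <- c(80, 95, 110)
  ba <- bland_altman(m, m)
  expect_equal(ba$mean_difference, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  set.seed(41)
  mgfr <- runif(2000, 60, 120)
  egfr <- mgfr + rnorm(2000, 5, 2)
  ba <- bland_altman(egfr, mgfr, "absolute")
  expect_equal(ba$mean_difference, 5, tolerance = 0.05)
  expect_equal(ba$loa_low, 5 - 1.96 * 2, tolerance = 0.05)
  expect_equal(ba$loa_high, 5 + 1.96 * 2, tolerance = 0.05)
  # ~95% of points inside the limits of agreement
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_lt(abs(100 * inside - 95), 2)
  # adding a constant shifts the mean and both limits by exactly c
  ba2 <- bland_altman(egfr + 3, mgfr, "absolute")
  expect_equal(ba2$mean_difference, ba$mean_difference + 3)
  expect_equal(ba2$loa_low, ba$loa_low + 3)
  expect_equal(ba2$loa_high, ba$loa_high + 3)
  # relative mode: 30% overestimation sits on the guide line
  bar <- bland_altman(1.3 * mgfr, mgfr, "relative")
  expect_equal(unique(round(bar$differences, 9)), 30)
  expect_equal(bar$guide_lines, c(-30, 30))
  # x-axis conventions
  expect_equal(bland_altman(egfr, mgfr)$x, mgfr)
  expect_equal(bland_altman(egfr, mgfr, x_axis = "mean")$x,
               (egfr + mgfr) / 2)
})
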