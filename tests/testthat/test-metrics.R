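test_that("median bias follows the sample median of differences", {
  expect_equal(median_bias(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(median_bias(c(8, 21, 35), c(10, 20, 30)), 1)   # {-2, 1, 5}
  expect_equal(median_bias(c(8, 21, 35, 49), c(10, 20, 30, 40)), 3)
  # antisymmetry
  set.seed(11)
  a <- rnorm(101, 90, 10); b <- rnorm(101, 90, 10)
  expect_equal(median_bias(a, b), -median_bias(b, a))
  expect_error(median_bias(1:3, 1:4), "paired")
  expect_error(median_bias(numeric(0), numeric(0)), "empty")
})

test_that("bootstrap CI of the median is reproducible and well-scaled", {
  d <- rep(4, 50)
  expect_equal(bias_ci(d, rep(0, 50), seed = 1), c(4, 4))
  set.seed(5)
  e <- rnorm(2000); m <- rep(0, 2000)
  ci1 <- bias_ci(e, m, seed = 9)
  ci2 <- bias_ci(e, m, seed = 9)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] < 0 && 0 < ci1[2])
  # asymptotic width of the median CI: 2 * 1.96 * 1.2533 / sqrt(2000) = 0.11
  expect_lt(abs(diff(ci1) - 0.11), 0.04)
  expect_error(bias_ci(e, m), "seed")
})

test_that("P30/P20 match brute-force counting", {
  expect_equal(p_accuracy(c(100, 100), c(100, 100)), 100)
  # 129 and 71 inside, 70 exactly on the -30% boundary (inclusive), 131 out
  expect_equal(p_accuracy(c(131, 129, 70, 71), rep(100, 4), 0.30), 75)
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:1000, 1)
    mgfr <- runif(n, 10, 150)
    egfr <- mgfr * exp(rnorm(n, 0, 0.3))
    for (tol in c(0.30, 0.20)) {
      brute <- 100 * sum(abs(egfr - mgfr) <= tol * mgfr) / n
      expect_equal(p_accuracy(egfr, mgfr, tol), brute, tolerance = 1e-12)
    }
    expect_lte(p_accuracy(egfr, mgfr, 0.20), p_accuracy(egfr, mgfr, 0.30))
  }
})

test_that("proportion CIs: Wald default with clipping, Wilson optional", {
  expect_equal(p_accuracy_ci(50, 100), c(50 - 1.96 * 5, 50 + 1.96 * 5),
               tolerance = 1e-3)
  expect_equal(p_accuracy_ci(100, 50), c(100, 100))
  # reproduces the printed interval pattern for P30 = 65.4%, n = 1892
  ci <- p_accuracy_ci(65.4, 1892)
  expect_lt(max(abs(ci - c(63.3, 67.6))), 0.1)
  w <- p_accuracy_ci(80, 200, method = "wilson")
  expect_true(w[1] < 80 && 80 < w[2])
})

test_that("IQR of the bias uses linear-interpolation quartiles", {
  egfr <- 100 + (1:8); mgfr <- rep(100, 8)
  iq <- iqr_bias(egfr, mgfr)
  expect_equal(unname(iq), c(3.5, 2.75, 6.25))
  expect_equal(iqr_bias(rep(103, 5), rep(100, 5)),
               c(width = 0, q1 = 3, q3 = 3))
  # width is invariant to a location shift
  set.seed(3)
  a <- rnorm(50, 90, 12); b <- rnorm(50, 90, 12)
  expect_equal(iqr_bias(a + 7, b)[["width"]], iqr_bias(a, b)[["width"]])
  expect_error(iqr_bias(1:3, 1:3), "4")
})

test_that("non-overlapping-CI rule: strict gaps only, symmetric", {
  row <- function(eq, lo, hi) {
    data.frame(equation = eq, stratum = "all",
               bias_lo = lo, bias_hi = hi)
  }
  # published whole-cohort intervals: Europe EKFC vs CKD-EPI are separated
  v <- compare_by_ci_overlap(row("EKFC", 1.59, 2.91),
                             row("CKD-EPI", 16.49, 18.47), "bias")
  expect_true(v$different)
  # USA EKFC vs r-LMR overlap on [-1.69, -1.65]
  v <- compare_by_ci_overlap(row("EKFC", -1.69, 2.24),
                             row("r-LMR", -5.08, -1.65), "bias")
  expect_false(v$different)
  # touching endpoints count as overlapping
  v <- compare_by_ci_overlap(row("A", 0, 1), row("B", 1, 2), "bias")
  expect_false(v$different)
  # symmetry
  a <- row("A", 0, 1); b <- row("B", 5, 6)
  expect_equal(compare_by_ci_overlap(a, b, "bias")$different,
               compare_by_ci_overlap(b, a, "bias")$different)
  b$stratum <- "male"
  expect_error(compare_by_ci_overlap(a, b, "bias"), "strata")
})

test_that("performance table on a known-truth cohort", {
  co <- make_exact_cohort(n = 300, seed = 8)
  pt <- performance_table(co, n_boot = 300, seed = 2)
  expect_equal(nrow(pt), 3)
  expect_setequal(pt$equation, c("EKFC", "CKD-EPI", "r-LMR"))
  ek <- pt[pt$equation == "EKFC", ]
  expect_equal(ek$bias, 0, tolerance = 1e-9)
  expect_equal(ek$p30, 100)
  expect_equal(ek$iqr, 0, tolerance = 1e-9)
  # the young-age overestimation of CKD-EPI appears by construction
  expect_gt(pt$bias[pt$equation == "CKD-EPI"], 0)
  # identity estimate row: degenerate CIs still bracket the point
  expect_true(ek$bias_lo <= ek$bias && ek$bias <= ek$bias_hi)
  # empty stratum yields an n = 0 row with absent metrics
  pt0 <- performance_table(co, equations = "EKFC",
                           strata = list(grp = factor(rep("x", nrow(co)),
                                                      levels = c("x", "y"))),
                           n_boot = 100, seed = 2)
  expect_equal(nrow(pt0), 1)  # absent level never materializes subjects
  lab <- rep(c("x", "y"), length.out = nrow(co))
  pt2 <- performance_table(co, equations = "EKFC",
                           strata = list(grp = lab), n_boot = 100, seed = 2)
  expect_equal(sum(pt2$n), nrow(co))
})
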