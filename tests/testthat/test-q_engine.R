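test_that("creatinine unit conversion uses 88.4 and round-trips", {
  expect_equal(scr_to_umol_l(0.90, "mg_dl"), 79.56)
  expect_equal(scr_to_mg_dl(88.4, "umol_l"), 1)
  x <- c(35.7, 61.88, 79.56, 450)
  expect_equal(scr_to_umol_l(scr_to_mg_dl(x, "umol_l"), "mg_dl"), x,
               tolerance = 1e-9)
  expect_error(scr_to_umol_l(-1, "mg_dl"), "positive")
})

test_that("European age polynomials hit their stated adult plateaus", {
  # ln(Q) polynomial at age 25, natural log, Q in umol/L
  expect_equal(q_poly_europe(25, "male", "umol_l"), 80.8645,
               tolerance = 1e-4)
  expect_lt(abs(q_poly_europe(25, "female", "mg_dl") - 0.70), 0.02)
  expect_lt(abs(q_poly_europe(25, "male", "mg_dl") - 0.90), 0.02)
})

test_that("the polynomial log term is the natural logarithm", {
  # with base-10 logs the male curve misses the plateau by a factor ~2.7
  lnq10 <- 3.200 + 0.259 * 25 - 0.543 * log10(25) - 0.00763 * 625 +
    0.0000790 * 15625
  expect_gt(exp(lnq10) / 88.4, 2)              # wrong reading blows up
  expect_lt(q_poly_europe(25, "male", "mg_dl"), 1)  # implementation does not
})

test_that("fixed adult Q-values match the published constants", {
  expect_equal(q_fixed("female", q_spec("europe"), "mg_dl"), 0.70)
  expect_equal(q_fixed("male", q_spec("europe"), "mg_dl"), 0.90)
  expect_equal(q_fixed("female", q_spec("us"), "mg_dl"), 0.73)
  expect_equal(q_fixed("male", q_spec("us"), "mg_dl"), 0.97)
  expect_lt(q_fixed("female", q_spec("us")), q_fixed("male", q_spec("us")))
})

test_that("gradual-change interpolation anchors at 12 and 25 exactly", {
  us <- q_spec("us")
  for (s in c("female", "male")) {
    expect_equal(q_interpolated(12, s, us), q_poly_europe(12, s),
                 tolerance = 1e-12)
    expect_equal(q_interpolated(25, s, us, "mg_dl"),
                 q_fixed(s, us, "mg_dl"), tolerance = 1e-12)
  }
  # below 12 the reference curve is used unchanged
  expect_equal(q_interpolated(8, "female", us), q_poly_europe(8, "female"),
               tolerance = 1e-12)
})

test_that("interpolation factor is linear in age between the anchors", {
  us <- q_spec("us")
  ref <- function(a) q_poly_europe(a, "male", "mg_dl")
  expected <- ref(18.5) * (1 + 0.5 * (0.97 / ref(25) - 1))
  expect_equal(q_interpolated(18.5, "male", us, "mg_dl"), expected,
               tolerance = 1e-12)
  expect_error(q_interpolated(20, "male", q_spec("europe")), "reference")
})

test_that("q_lookup dispatches across regimes and is continuous at 25", {
  eu <- q_spec("europe"); us <- q_spec("us")
  expect_equal(q_lookup(40, "male", eu, "mg_dl")$q, 0.9)
  expect_equal(q_lookup(40, "male", eu)$mode, "fixed")
  expect_equal(q_lookup(20, "male", eu)$mode, "polynomial")
  expect_equal(q_lookup(20, "male", us)$mode, "interpolated")
  expect_error(q_lookup(1.5, "male", eu), "age")
  eps <- 1e-9
  expect_lt(abs(q_lookup(25 - eps, "female", us)$q -
                q_lookup(25 + eps, "female", us)$q), 1e-6)
  # European curve meets its rounded plateau within the rounding tolerance
  expect_lt(abs(q_lookup(25 - eps, "male", eu, "mg_dl")$q -
                q_lookup(25 + eps, "male", eu, "mg_dl")$q), 0.02)
  # fixed mode overrides the curve at all ages
  expect_equal(q_lookup(c(5, 20, 60), "male", eu, "mg_dl",
                        q_mode = "fixed")$q, rep(0.9, 3))
})

test_that("Q is positive everywhere and ordered by sex from age 12", {
  ages <- seq(2, 100, by = 0.5)
  for (pop in c("europe", "us")) {
    spec <- q_spec(pop)
    qf <- q_lookup(ages, rep("female", length(ages)), spec)$q
    qm <- q_lookup(ages, rep("male", length(ages)), spec)$q
    expect_true(all(qf > 0) && all(qm > 0))
    adol <- ages >= 12
    expect_true(all(qm[adol] >= qf[adol]))
  }
  # male polynomial rises monotonically from 12 to the plateau
  g <- seq(12, 25, by = 0.05)
  qm <- q_poly_europe(g, "male")
  expect_equal(which.max(qm), length(g))
  expect_true(qm[1] < q_poly_europe(20, "male") &&
              q_poly_europe(20, "male") < qm[length(g)])
})

test_that("rescaling reconciles units before dividing", {
  expect_equal(rescale_creatinine(0.90, 0.90, "mg_dl", "mg_dl"), 1)
  expect_equal(rescale_creatinine(79.56, 0.90, "umol_l", "mg_dl"), 1)
  expect_equal(rescale_creatinine(1.35, 0.90, "mg_dl", "mg_dl"), 1.5)
  expect_error(rescale_creatinine(-1, 0.9), "positive")
  expect_error(rescale_creatinine(1, 0), "positive")
})

test_that("custom populations register through the JSON schema", {
  custom <- q_spec_from_list(list(
    label = "custom", plateau_mg_dl = list(female = 0.75, male = 0.95),
    reference = "europe"))
  expect_s3_class(custom, "q_spec")
  expect_equal(q_interpolated(25, "male", custom, "mg_dl"), 0.95,
               tolerance = 1e-12)
  expect_error(q_spec_from_list(list(
    label = "bad", plateau_mg_dl = list(female = 0.9, male = 0.8))),
    "female plateau")
  expect_error(q_spec("atlantis"), "unknown Q population")
})
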