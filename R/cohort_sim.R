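#' Cohort generative profiles
#'
#' A `cohort_profile` holds the generative parameters for a synthetic
#' validation cohort: sample size, truncated-normal age and mGFR marginals,
#' sex and race mix, and a multiplicative log-normal creatinine noise level.
#' Serum creatinine is generated from mGFR by inverting the EKFC equation
#' (see [scr_from_mgfr()]), so with `sigma = 0` the generating equation
#' recovers mGFR exactly — a known-truth mode used throughout the tests.
#'
#' The built-in registry emulates the published cohort profiles of a
#' European/US young-adult validation study: Europe n = 1892 (age 20.7 +/-
#' 2.1, mGFR 89.5 +/- 28.9, all non-Black), USA n = 474 (age 22.2 +/- 2.2,
#' mGFR 61.5 +/- 35.3, 37 Black), plus the US non-Black (437) and US Black
#' (37) sub-profiles. The printed mean is matched by the *truncated*
#' distribution: the latent normal mean is solved so that the truncated mean
#' equals the profile mean (printed SD kept as the latent SD); see the
#' methods vignette for why.
#'
#' @param label profile name.
#' @param n cohort size.
#' @param age_mean,age_sd,age_lo,age_hi truncated-normal age parameters
#'   (years).
#' @param mgfr_mean,mgfr_sd,mgfr_lo,mgfr_hi truncated-normal mGFR parameters
#'   (mL/min/1.73 m^2).
#' @param sex_fraction_female proportion female in \[0, 1\].
#' @param race_fraction_black proportion Black in \[0, 1\].
#' @param sigma SD of the multiplicative log-normal creatinine noise (log
#'   scale); 0 gives the zero-noise known-truth mode.
#' @param q_population Q registry key used both to invert creatinine and as
#'   the cohort's natural analysis spec.
#' @return object of class `cohort_profile`.
#' @export
cohort_profile <- function(label, n,
                           age_mean, age_sd, age_lo = 18, age_hi = 25,
                           mgfr_mean, mgfr_sd, mgfr_lo = 5, mgfr_hi = 250,
                           sex_fraction_female = 0.5,
                           race_fraction_black = 0,
                           sigma = 0.15,
                           q_population = "europe") {
  p <- structure(list(
    label = label, n = as.integer(n),
    age = list(mean = age_mean, sd = age_sd, lo = age_lo, hi = age_hi),
    mgfr = list(mean = mgfr_mean, sd = mgfr_sd, lo = mgfr_lo, hi = mgfr_hi),
    sex_fraction_female = sex_fraction_female,
    race_fraction_black = race_fraction_black,
    sigma = sigma, q_population = q_population
  ), class = "cohort_profile")
  validate_profile(p)
}

validate_profile <- function(p) {
  stopifnot(p$n > 0, p$sigma >= 0,
            p$sex_fraction_female >= 0, p$sex_fraction_female <= 1,
            p$race_fraction_black >= 0, p$race_fraction_black <= 1)
  for (d in list(p$age, p$mgfr)) {
    stopifnot(d$sd >= 0, d$lo < d$hi, d$mean > d$lo, d$mean < d$hi)
  }
  p
}

#' @rdname cohort_profile
#' @export
profile_registry <- function() {
  list(
    `Europe-young` = cohort_profile(
      "Europe-young", n = 1892, age_mean = 20.7, age_sd = 2.1,
      mgfr_mean = 89.5, mgfr_sd = 28.9,
      race_fraction_black = 0, q_population = "europe"),
    `US-young` = cohort_profile(
      "US-young", n = 474, age_mean = 22.2, age_sd = 2.2,
      mgfr_mean = 61.5, mgfr_sd = 35.3,
      race_fraction_black = 37 / 474, q_population = "us"),
    `US-young-nonblack` = cohort_profile(
      "US-young-nonblack", n = 437, age_mean = 22.2, age_sd = 2.2,
      mgfr_mean = 61.5, mgfr_sd = 35.3,
      race_fraction_black = 0, q_population = "us"),
    `US-young-black` = cohort_profile(
      "US-young-black", n = 37, age_mean = 22.2, age_sd = 2.2,
      mgfr_mean = 61.5, mgfr_sd = 35.3,
      race_fraction_black = 1, q_population = "us")
  )
}

# Latent mean of a truncated normal whose truncated mean equals `target`.
# Solved by uniroot on the closed-form truncated-normal mean.
latent_mean_for_truncated <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  # tmean is continuous and increasing in mu; expand the bracket outward
  # from the target until it straddles the root (wide fixed brackets
  # underflow the normal tail ratio)
  lower <- target; upper <- target
  for (i in seq_len(50)) {
    v <- tmean(lower)
    if (!is.finite(v) || v <= target) break
    lower <- lower - sd
  }
  for (i in seq_len(50)) {
    v <- tmean(upper)
    if (!is.finite(v) || v >= target) break
    upper <- upper + sd
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 lower = lower, upper = upper, tol = 1e-10,
                 extendInt = "upX")$root
}

# Inverse-CDF sampling of a truncated normal (no rejection, no clipping).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  mu <- latent_mean_for_truncated(mean, sd, lo, hi)
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

#' Generate serum creatinine from measured GFR
#'
#' Inverts the EKFC closed form — SCr = Q * (107.3 * 0.990^max(age-40,0) /
#' mGFR)^(1/a), branch chosen so that high GFR maps to SCr/Q < 1 — then
#' applies multiplicative log-normal noise exp(e), e ~ N(0, sigma^2). The
#' noise is median-unbiased on the log scale, so the generating equation's
#' median bias is ~0 for sigma > 0 and exactly 0 for sigma = 0.
#'
#' @param mgfr measured GFR in mL/min/1.73 m^2, > 0.
#' @param age,sex subject covariates (vectorized).
#' @param spec [q_spec()] of the generating population.
#' @param sigma log-scale noise SD, >= 0.
#' @param seed integer seed (only used when `sigma > 0`).
#' @return serum creatinine in umol/L.
#' @export
scr_from_mgfr <- function(mgfr, age, sex, spec = q_spec("europe"),
                          sigma = 0, seed = 1L) {
  stopifnot(sigma >= 0)
  scr <- egfr_ekfc_invert(mgfr, age, sex, spec = spec)
  if (sigma > 0) {
    eps <- with_seed(seed, stats::rnorm(length(scr), 0, sigma))
    scr <- scr * exp(eps)
  }
  scr
}

#' Generate a synthetic cohort from a profile
#'
#' Draws age and mGFR independently from the profile's truncated normals
#' (inverse-CDF sampling — nothing is clipped), assigns sex and race by
#' exact proportions (largest-remainder counts, then a seeded shuffle), and
#' derives serum creatinine through [scr_from_mgfr()]. All randomness flows
#' from `seed` through fixed per-column substreams, so the same
#' (profile, seed) pair reproduces the cohort exactly and adding columns
#' never perturbs existing ones.
#'
#' @param profile a [cohort_profile()] or a name in [profile_registry()].
#' @param seed integer master seed.
#' @param n optional override of the profile's sample size.
#' @return data frame with columns `id`, `cohort`, `age`, `sex`, `race`,
#'   `scr_umol_l`, `mgfr`, and attributes `profile` and `seed`.
#' @export
generate_cohort <- function(profile, seed = 1L, n = NULL) {
  if (is.character(profile)) {
    reg <- profile_registry()
    if (!profile %in% names(reg)) {
      stop("unknown profile '", profile, "'; available: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    profile <- reg[[profile]]
  }
  stopifnot(inherits(profile, "cohort_profile"))
  validate_profile(profile)
  n <- if (is.null(n)) profile$n else as.integer(n)
  age <- with_seed(substream_seed(seed, 1L),
                   rtruncnorm(n, profile$age$mean, profile$age$sd,
                              profile$age$lo, profile$age$hi))
  mgfr <- with_seed(substream_seed(seed, 2L),
                    rtruncnorm(n, profile$mgfr$mean, profile$mgfr$sd,
                               profile$mgfr$lo, profile$mgfr$hi))
  sex <- with_seed(substream_seed(seed, 3L),
                   sample(exact_mix(n, profile$sex_fraction_female,
                                    c("female", "male"))))
  race <- with_seed(substream_seed(seed, 4L),
                    sample(exact_mix(n, profile$race_fraction_black,
                                     c("Black", "non-Black"))))
  spec <- q_spec(profile$q_population)
  scr <- scr_from_mgfr(mgfr, age, sex, spec = spec, sigma = profile$sigma,
                       seed = substream_seed(seed, 5L))
  out <- data.frame(
    id = sprintf("%s-%05d", gsub("[^A-Za-z0-9]+", "", profile$label),
                 seq_len(n)),
    cohort = profile$label,
    age = age, sex = sex, race = race,
    scr_umol_l = scr, mgfr = mgfr,
    stringsAsFactors = FALSE
  )
  attr(out, "profile") <- profile
  attr(out, "seed") <- as.integer(seed)
  out
}

# n subjects split between two groups matching fraction `frac` of group 1 as
# closely as possible (rounding half away from zero keeps tiny groups, e.g.
# 37/474 Black -> exactly 37).
exact_mix <- function(n, frac, labels) {
  n1 <- round(n * frac)
  c(rep(labels[1], n1), rep(labels[2], n - n1))
}
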