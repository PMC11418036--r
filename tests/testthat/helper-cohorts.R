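# Small zero-noise cohort: truth is known exactly because creatinine is the
# EKFC inverse of mgfr.
make_exact_cohort <- function(n = 200, seed = 42, population = "europe") {
  prof <- cohort_profile(
    label = "exact-test", n = n,
    age_mean = 21, age_sd = 2, mgfr_mean = 90, mgfr_sd = 25,
    sigma = 0, q_population = population)
  generate_cohort(prof, seed = seed)
}

# Minimal hand-built cohort data frame for unit tests.
make_tiny_cohort <- function() {
  data.frame(
    id = c("a", "b", "c"),
    age = c(20, 22, 24),
    sex = c("female", "male", "male"),
    scr_umol_l = c(60, 80, 95),
    mgfr = c(95, 100, 80),
    stringsAsFactors = FALSE
  )
}
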