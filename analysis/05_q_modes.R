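#!/usr/bin/env Rscript
# Polynomial versus fixed Q-values for the rescaled-creatinine equations in
# 18-25 year olds: the cross-sectional impact of replacing the age
# polynomial by the adult plateau.

suppressPackageStartupMessages(library(gfryoung))
seed <- 20260919
dir.create("results/q_modes", showWarnings = FALSE, recursive = TRUE)

co <- read_cohort_csv("results/cohorts/Europe-young.csv")
tabs <- lapply(c(polynomial = "auto", fixed = "fixed"), function(qm) {
  performance_table(co, equations = c("EKFC", "r-LMR"), q_mode = qm,
                    seed = seed, n_boot = 2000)
})
tabs$polynomial$q_mode <- "polynomial"; tabs$fixed$q_mode <- "fixed"
out <- rbind(tabs$polynomial, tabs$fixed)
write.csv(out, "results/q_modes/q_mode_comparison.csv", row.names = FALSE)

for (eq in c("EKFC", "r-LMR")) {
  a <- out[out$equation == eq & out$q_mode == "polynomial", ]
  b <- out[out$equation == eq & out$q_mode == "fixed", ]
  message(sprintf(
    "%-6s bias: polynomial %5.2f (%5.2f; %5.2f) vs fixed %5.2f (%5.2f; %5.2f); P30 %.1f vs %.1f",
    eq, a$bias, a$bias_lo, a$bias_hi, b$bias, b$bias_lo, b$bias_hi,
    a$p30, b$p30))
}
message("In this age band the two Q modes differ only through the ",
        "0.70/0.90 plateau rounding, so global performance is essentially ",
        "unchanged; the polynomial keeps the child-adult transition smooth.")
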