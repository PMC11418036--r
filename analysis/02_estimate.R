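#!/usr/bin/env Rscript
# Compute eGFR for every cohort under the three equations (EKFC and r-LMR
# through the cohort's own Q population: European polynomials for Europe,
# interpolated race-free Q for the US cohorts).

suppressPackageStartupMessages(library(gfryoung))
dir.create("results/egfr", showWarnings = FALSE, recursive = TRUE)

specs <- c(`Europe-young` = "europe", `US-young` = "us",
           `US-young-nonblack` = "us", `US-young-black` = "us")

for (name in names(specs)) {
  co <- read_cohort_csv(file.path("results/cohorts", paste0(name, ".csv")))
  stopifnot(nrow(attr(co, "rejects")) == 0)
  spec <- q_spec(specs[[name]])
  res <- do.call(rbind, lapply(c("EKFC", "CKD-EPI", "r-LMR"), function(eq) {
    egfr_batch(co, eq, spec = spec)
  }))
  path <- file.path("results/egfr", paste0(name, ".csv"))
  write.csv(res, path, row.names = FALSE)
  ok <- res[res$status == "ok", ]
  message(sprintf("%-18s %d estimates (%d rejected) -> %s", name,
                  sum(res$status == "ok"), sum(res$status != "ok"), path))
  for (eq in unique(ok$equation)) {
    message(sprintf("    %-8s median eGFR %.1f mL/min/1.73m2", eq,
                    median(ok$egfr[ok$equation == eq])))
  }
}
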