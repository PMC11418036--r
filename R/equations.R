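# Equation coefficients live in one table so transcription is auditable.
# EKFC: eGFR = 107.3 / (SCr/Q)^a * 0.990^max(age-40, 0),
#        a = 0.322 for SCr/Q < 1, 1.132 otherwise.
# CKD-EPI 2021 (race-free): 142 * min(SCr/k,1)^a * max(SCr/k,1)^-1.200
#        * 0.9938^age * (1.012 if female); k = 0.7 F / 0.9 M mg/dL,
#        a = -0.241 F / -0.302 M.
# r-LMR: LMR re-expressed in rescaled creatinine. With rho = SCr/Q and the
#        European adult reference concentrations (61.88 F / 79.56 M umol/L)
#        mapping rho back to the native LMR creatinine scale, the native
#        breakpoints 150/180 umol/L become rho* = 150/61.88 (F), 180/79.56
#        (M): eGFR = exp(X - 0.0158*age + 0.438*ln(age)) with
#        X = b0 + b1*(SCr* - rho*Qref) below rho*, X = b0 - 0.926*ln(rho/rho*)
#        above, continuous at rho*.
EGFR_CONSTANTS <- list(
  ekfc = list(intercept = 107.3, alpha_low = 0.322, alpha_high = 1.132,
              age_knot = 40, age_factor = 0.990),
  ckdepi2021 = list(
    intercept = 142, exp_high = -1.200, age_factor = 0.9938,
    female_factor = 1.012,
    kappa_mg_dl = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.241, male = -0.302)
  ),
  rlmr = list(
    b0 = c(female = 2.50, male = 2.56),
    slope_umol = c(female = 0.0121, male = 0.00968),  # per umol/L below break
    break_umol = c(female = 150, male = 180),
    ref_q_umol = c(female = 0.70, male = 0.90) * 88.4,
    log_slope = 0.926, age_lin = 0.0158, age_log = 0.438
  )
)

#' EKFC equation
#'
#' Estimated GFR from rescaled serum creatinine: eGFR = 107.3 / (SCr/Q)^a *
#' 0.990^max(age - 40, 0), with exponent a = 0.322 below SCr/Q = 1 and 1.132
#' above (continuous at the branch point), i.e. two splines with a knot at
#' age 40. The Q-value is resolved through [q_lookup()] (age polynomial /
#' interpolated curve below 25, fixed adult plateau above, or fixed at all
#' ages with `q_mode = "fixed"`).
#'
#' @param scr serum creatinine, vectorized.
#' @param age years, >= 2.
#' @param sex `"female"`/`"male"` (or F/M).
#' @param spec a [q_spec()] naming the reference population.
#' @param q_mode `"auto"` or `"fixed"`, see [q_lookup()].
#' @param scr_unit unit of `scr`.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ekfc(79.56, 22, "male")        # SCr close to Q -> near 107.3
#' egfr_ekfc(0.9, 60, "male", scr_unit = "mg_dl")
#' @export
egfr_ekfc <- function(scr, age, sex, spec = q_spec("europe"),
                      q_mode = c("auto", "fixed"),
                      scr_unit = c("umol_l", "mg_dl")) {
  q_mode <- match.arg(q_mode); scr_unit <- match.arg(scr_unit)
  k <- EGFR_CONSTANTS$ekfc
  ql <- q_lookup(age, sex, spec, unit = "umol_l", q_mode = q_mode)
  rho <- rescale_creatinine(scr, ql$q, scr_unit = scr_unit, q_unit = "umol_l")
  n <- length(rho)
  age <- rep_len(age, n)
  alpha <- ifelse(rho < 1, k$alpha_low, k$alpha_high)
  k$intercept / rho^alpha * k$age_factor^pmax(age - k$age_knot, 0)
}

#' Race-free CKD-EPI 2021 equation
#'
#' eGFR = 142 * min(SCr/kappa, 1)^alpha * max(SCr/kappa, 1)^-1.200 *
#' 0.9938^age * 1.012 (if female), with kappa = 0.7 (F) / 0.9 (M) mg/dL and
#' alpha = -0.241 (F) / -0.302 (M). An adult-only equation: ages below 18 are
#' rejected (it overestimates GFR massively in children).
#'
#' @inheritParams egfr_ekfc
#' @param age years, >= 18.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi2021 <- function(scr, age, sex,
                            scr_unit = c("umol_l", "mg_dl")) {
  scr_unit <- match.arg(scr_unit)
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("CKD-EPI is an adult equation: age must be >= 18 years",
         call. = FALSE)
  }
  k <- EGFR_CONSTANTS$ckdepi2021
  sex <- as_sex(sex)
  scr_mgdl <- scr_to_mg_dl(scr, scr_unit)
  n <- max(length(scr_mgdl), length(age), length(sex))
  scr_mgdl <- rep_len(scr_mgdl, n); age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  kappa <- unname(k$kappa_mg_dl[sex])
  alpha <- unname(k$alpha[sex])
  ratio <- scr_mgdl / kappa
  k$intercept * pmin(ratio, 1)^alpha * pmax(ratio, 1)^k$exp_high *
    k$age_factor^age * ifelse(sex == "female", k$female_factor, 1)
}

#' Re-expressed Lund-Malmo Revised (r-LMR) equation
#'
#' The Lund-Malmo Revised equation rewritten on the rescaled-creatinine
#' scale: with rho = SCr/Q, eGFR = exp(X - 0.0158*age + 0.438*ln(age)),
#' where X is linear in creatinine below a sex-specific rescaled breakpoint
#' (150/180 umol/L on the native scale, i.e. rho = 2.424 F / 2.263 M) and
#' log-linear with slope -0.926 above it; the two regimes join continuously.
#' Rescaling through the population Q makes the equation applicable beyond
#' the population it was developed in.
#'
#' @inheritParams egfr_ekfc
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_rlmr <- function(scr, age, sex, spec = q_spec("europe"),
                      q_mode = c("auto", "fixed"),
                      scr_unit = c("umol_l", "mg_dl")) {
  q_mode <- match.arg(q_mode); scr_unit <- match.arg(scr_unit)
  k <- EGFR_CONSTANTS$rlmr
  ql <- q_lookup(age, sex, spec, unit = "umol_l", q_mode = q_mode)
  rho <- rescale_creatinine(scr, ql$q, scr_unit = scr_unit, q_unit = "umol_l")
  n <- length(rho)
  age <- rep_len(age, n); sex <- rep_len(as_sex(sex), n)
  # creatinine mapped back to the native (European adult) scale
  cr_native <- rho * unname(k$ref_q_umol[sex])
  brk <- unname(k$break_umol[sex])
  b0 <- unname(k$b0[sex])
  slope <- unname(k$slope_umol[sex])
  x <- ifelse(cr_native < brk,
              b0 + slope * (brk - cr_native),
              b0 - k$log_slope * log(cr_native / brk))
  exp(x - k$age_lin * age + k$age_log * log(age))
}

#' Apply one equation to a whole cohort
#'
#' Order-preserving batch evaluation: one output row per subject. Subjects
#' failing an equation's preconditions (e.g. age < 18 under CKD-EPI, missing
#' or non-positive creatinine) are reported with a reason in the `status` /
#' `reason` columns rather than dropped; their `egfr` is `NA`.
#'
#' @param cohort data frame with columns `id`, `age`, `sex`, `scr_umol_l`
#'   (or `scr_mg_dl`), as produced by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param equation `"EKFC"`, `"CKD-EPI"` or `"r-LMR"`.
#' @inheritParams egfr_ekfc
#' @return data frame: `id`, `equation`, `egfr`, `q_used_umol_l`, `q_mode`,
#'   `status` (`"ok"`/`"rejected"`), `reason`.
#' @export
egfr_batch <- function(cohort, equation = c("EKFC", "CKD-EPI", "r-LMR"),
                       spec = q_spec("europe"), q_mode = c("auto", "fixed")) {
  equation <- match.arg(equation); q_mode <- match.arg(q_mode)
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort must be a non-empty data frame", call. = FALSE)
  }
  scr <- cohort_scr_umol(cohort)
  n <- nrow(cohort)
  out <- data.frame(
    id = as.character(cohort$id), equation = equation,
    egfr = NA_real_, q_used_umol_l = NA_real_, q_mode = NA_character_,
    status = "ok", reason = NA_character_, stringsAsFactors = FALSE
  )
  age <- cohort$age
  sex <- as_sex(cohort$sex)
  bad <- !is.finite(scr) | scr <= 0
  out$reason[bad] <- "non-positive or missing creatinine"
  bad_age <- !is.finite(age) | age < 2
  out$reason[!bad & bad_age] <- "age below 2 years"
  if (equation == "CKD-EPI") {
    young <- !bad & !bad_age & age < 18
    out$reason[young] <- "age below 18 years (CKD-EPI is adult-only)"
    bad_age <- bad_age | young
  }
  bad <- bad | bad_age
  out$status[bad] <- "rejected"
  ok <- !bad
  if (any(ok)) {
    if (equation == "CKD-EPI") {
      out$egfr[ok] <- egfr_ckdepi2021(scr[ok], age[ok], sex[ok])
      out$q_mode[ok] <- "n/a"
    } else {
      ql <- q_lookup(age[ok], sex[ok], spec, unit = "umol_l", q_mode = q_mode)
      out$q_used_umol_l[ok] <- ql$q
      out$q_mode[ok] <- ql$mode
      fn <- if (equation == "EKFC") egfr_ekfc else egfr_rlmr
      out$egfr[ok] <- fn(scr[ok], age[ok], sex[ok], spec = spec,
                         q_mode = q_mode)
    }
  }
  out
}

# Resolve the creatinine column of a cohort data frame to umol/L.
cohort_scr_umol <- function(cohort) {
  has_u <- "scr_umol_l" %in% names(cohort)
  has_m <- "scr_mg_dl" %in% names(cohort)
  if (has_u && has_m) {
    stop("cohort must carry exactly one of scr_umol_l / scr_mg_dl",
         call. = FALSE)
  }
  if (has_u) as.numeric(cohort$scr_umol_l)
  else if (has_m) as.numeric(cohort$scr_mg_dl) * CREAT_UMOL_PER_MGDL
  else stop("cohort has no creatinine column (scr_umol_l or scr_mg_dl)",
            call. = FALSE)
}

#' Invert the EKFC equation for a target GFR
#'
#' Closed-form solve of the EKFC equation for serum creatinine: SCr =
#' Q * (107.3 * 0.990^max(age-40,0) / GFR)^(1/a), with the branch chosen so
#' that GFR above the age-adjusted intercept maps to SCr/Q < 1. Used by the
#' cohort generator and in round-trip consistency checks.
#'
#' @param gfr target GFR in mL/min/1.73 m^2, > 0.
#' @inheritParams egfr_ekfc
#' @return serum creatinine in umol/L.
#' @export
egfr_ekfc_invert <- function(gfr, age, sex, spec = q_spec("europe"),
                             q_mode = c("auto", "fixed")) {
  q_mode <- match.arg(q_mode)
  check_positive(gfr, "GFR")
  k <- EGFR_CONSTANTS$ekfc
  ql <- q_lookup(age, sex, spec, unit = "umol_l", q_mode = q_mode)
  n <- max(length(gfr), length(ql$q))
  gfr <- rep_len(gfr, n); age <- rep_len(age, n)
  top <- k$intercept * k$age_factor^pmax(age - k$age_knot, 0)
  alpha <- ifelse(gfr > top, k$alpha_low, k$alpha_high)
  ql$q * (top / gfr)^(1 / alpha)
}
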