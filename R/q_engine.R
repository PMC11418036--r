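#' Q-value specifications
#'
#' A `q_spec` describes how the median serum creatinine of a healthy
#' reference population (the Q-value) depends on age and sex. Between ages 2
#' and 25 the European specification uses sex-specific polynomials in age for
#' ln(Q in umol/L); beyond 25 Q is a fixed adult plateau. Populations without
#' their own pediatric curve (e.g. the race-free US values) carry a reference
#' spec whose curve is followed until age 12 and then blended linearly into
#' the population's own adult plateau at 25 (see [q_interpolated()]).
#'
#' Built-in specifications are stored as a versioned JSON registry shipped
#' with the package (`system.file("extdata", "q_specs.json", package =
#' "gfryoung")`); users may register populations with the same schema via
#' `q_spec_from_list()`.
#'
#' @param population key in the registry, e.g. `"europe"`, `"us"`.
#' @return an object of class `q_spec`.
#' @examples
#' eu <- q_spec("europe")
#' us <- q_spec("us")
#' q_lookup(20, "male", eu)
#' @export
q_spec <- function(population) {
  reg <- q_registry()
  if (!population %in% names(reg)) {
    stop("unknown Q population '", population, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[population]]
}

#' @rdname q_spec
#' @export
q_registry <- function() {
  reg <- q_registry_env$registry
  if (is.null(reg)) {
    path <- system.file("extdata", "q_specs.json", package = "gfryoung")
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    pops <- doc$populations
    reg <- list()
    for (key in names(pops)) {
      reg[[key]] <- q_spec_from_list(c(pops[[key]], list(key = key)),
                                     registry = reg)
    }
    q_registry_env$registry <- reg
  }
  reg
}

q_registry_env <- new.env(parent = emptyenv())

#' @rdname q_spec
#' @param x list mirroring one registry entry: `label`, optional
#'   `poly_coeffs` (per-sex 5-vectors: intercept, age, ln(age), age^2, age^3),
#'   `plateau_mg_dl` (per-sex), optional `reference` (a `q_spec` or a key into
#'   `registry`).
#' @param registry named list used to resolve a character `reference`.
#' @export
q_spec_from_list <- function(x, registry = q_registry()) {
  spec <- structure(list(
    key = x$key %||% x$label,
    label = x$label,
    poly_coeffs = x$poly_coeffs,
    plateau_mg_dl = unlist(x$plateau_mg_dl)[c("female", "male")],
    reference = NULL
  ), class = "q_spec")
  if (!is.null(x$reference)) {
    spec$reference <- if (inherits(x$reference, "q_spec")) x$reference
                      else registry[[x$reference]]
    if (is.null(spec$reference)) {
      stop("reference population '", x$reference, "' not found", call. = FALSE)
    }
  }
  validate_q_spec(spec)
}

validate_q_spec <- function(spec) {
  pl <- spec$plateau_mg_dl
  if (any(is.na(pl)) || any(pl <= 0)) {
    stop("q_spec needs strictly positive female and male plateau values",
         call. = FALSE)
  }
  if (pl[["female"]] >= pl[["male"]]) {
    stop("female plateau must be below male plateau", call. = FALSE)
  }
  if (!is.null(spec$poly_coeffs)) {
    stopifnot(all(c("female", "male") %in% names(spec$poly_coeffs)),
              all(lengths(spec$poly_coeffs[c("female", "male")]) == 5L))
  } else if (is.null(spec$reference)) {
    stop("q_spec without an age polynomial needs a reference spec for ages < 25",
         call. = FALSE)
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.q_spec <- function(x, ...) {
  cat("<q_spec>", x$label, "\n")
  cat("  plateau (mg/dL): female", x$plateau_mg_dl[["female"]],
      "/ male", x$plateau_mg_dl[["male"]], "\n")
  cat("  age 2-25 curve:",
      if (!is.null(x$poly_coeffs)) "own polynomial"
      else paste0("interpolated from '", x$reference$label, "'"), "\n")
  invisible(x)
}

#' European age polynomial for the Q-value
#'
#' Evaluates the sex-specific polynomial ln(Q) = b0 + b1*age + b2*ln(age) +
#' b3*age^2 + b4*age^3 on ages 2-25 (Q in umol/L; the log term is the natural
#' logarithm — with base-10 logs the curve misses the adult plateau by a
#' factor of ~2.7). The curves level off near 0.70 (female) / 0.90 (male)
#' mg/dL at age 25.
#'
#' @param age years, in \[2, 25\]; vectorized.
#' @param sex `"female"`/`"male"` (or F/M), recycled against age.
#' @param unit output unit, `"umol_l"` (default) or `"mg_dl"`.
#' @param spec a `q_spec` carrying age polynomials (default European).
#' @return Q-values in `unit`.
#' @examples
#' scr_to_mg_dl(q_poly_europe(25, "male"))   # ~0.915
#' scr_to_mg_dl(q_poly_europe(25, "female")) # ~0.706
#' @export
q_poly_europe <- function(age, sex, unit = c("umol_l", "mg_dl"),
                          spec = q_spec("europe")) {
  unit <- match.arg(unit)
  check_age_range(age, 2, 25)
  sex <- as_sex(sex)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (is.null(spec$poly_coeffs)) {
    stop("spec '", spec$label, "' has no age polynomial", call. = FALSE)
  }
  lnq <- numeric(n)
  for (s in c("female", "male")) {
    idx <- sex == s
    if (!any(idx)) next
    b <- as.numeric(spec$poly_coeffs[[s]])
    a <- age[idx]
    lnq[idx] <- b[1] + b[2] * a + b[3] * log(a) + b[4] * a^2 + b[5] * a^3
  }
  q <- exp(lnq)
  if (unit == "mg_dl") q / CREAT_UMOL_PER_MGDL else q
}

#' Fixed adult Q-value
#'
#' Returns the adult plateau concentration of the spec for the given sex
#' (0.70/0.90 mg/dL Europe; 0.73/0.97 mg/dL race-free US).
#'
#' @inheritParams q_poly_europe
#' @export
q_fixed <- function(sex, spec = q_spec("europe"),
                    unit = c("umol_l", "mg_dl")) {
  unit <- match.arg(unit)
  sex <- as_sex(sex)
  q_mgdl <- unname(spec$plateau_mg_dl[sex])
  if (unit == "umol_l") q_mgdl * CREAT_UMOL_PER_MGDL else q_mgdl
}

#' Gradual-change Q interpolation for a new population (ages 2-25)
#'
#' For a population with known adult plateau but no pediatric curve, the
#' reference (European) curve is used unchanged until age 12 — healthy
#' children are assumed to share the same average serum creatinine — and is
#' then multiplied by a factor linear in age, equal to 1 at age 12 and to the
#' ratio (population adult plateau) / (reference curve at 25) at age 25. The
#' ratio is anchored to the reference polynomial's value at 25 (not the
#' rounded plateau) so the interpolated curve meets the population's adult
#' plateau exactly at 25, avoiding a jump at the adult transition.
#'
#' @inheritParams q_poly_europe
#' @param spec a `q_spec` with a `reference` spec.
#' @export
q_interpolated <- function(age, sex, spec, unit = c("umol_l", "mg_dl")) {
  unit <- match.arg(unit)
  if (is.null(spec$reference)) {
    stop("q_interpolated needs a spec with a reference population",
         call. = FALSE)
  }
  check_age_range(age, 2, 25)
  sex <- as_sex(sex)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  ref <- q_poly_europe(age, sex, unit = "umol_l", spec = spec$reference)
  ref25 <- q_poly_europe(rep(25, n), sex, unit = "umol_l",
                         spec = spec$reference)
  plateau <- q_fixed(sex, spec, unit = "umol_l")
  frac <- pmax(0, (age - 12) / (25 - 12))
  factor <- 1 + frac * (plateau / ref25 - 1)
  q <- ref * factor
  if (unit == "mg_dl") q / CREAT_UMOL_PER_MGDL else q
}

#' Q-value lookup across the full age range
#'
#' Dispatches across the three regimes: ages 2-25 use the population's age
#' curve (own polynomial, or gradual-change interpolation when the spec has a
#' reference population); ages above 25 use the fixed adult plateau. With
#' `q_mode = "fixed"` the plateau is used at all ages (the fixed-Q variant of
#' the EKFC equation). Ages below 2 are rejected.
#'
#' @inheritParams q_poly_europe
#' @param age years, >= 2; vectorized.
#' @param q_mode `"auto"` (curve below 25, plateau above) or `"fixed"`
#'   (plateau at every age).
#' @return list with components `q` (numeric, in `unit`) and `mode`
#'   (character: `"polynomial"`, `"interpolated"` or `"fixed"` per element).
#' @export
q_lookup <- function(age, sex, spec = q_spec("europe"),
                     unit = c("umol_l", "mg_dl"),
                     q_mode = c("auto", "fixed")) {
  unit <- match.arg(unit)
  q_mode <- match.arg(q_mode)
  if (any(!is.finite(age)) || any(age < 2)) {
    stop("age must be >= 2 years (infancy is outside the Q-value system)",
         call. = FALSE)
  }
  sex <- as_sex(sex)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  q <- numeric(n)
  mode <- character(n)
  if (q_mode == "fixed") {
    q <- q_fixed(sex, spec, unit = unit)
    mode[] <- "fixed"
    return(list(q = q, mode = mode))
  }
  young <- age <= 25
  if (any(young)) {
    if (is.null(spec$reference)) {
      q[young] <- q_poly_europe(age[young], sex[young], unit = unit,
                                spec = spec)
      mode[young] <- "polynomial"
    } else {
      q[young] <- q_interpolated(age[young], sex[young], spec, unit = unit)
      mode[young] <- "interpolated"
    }
  }
  if (any(!young)) {
    q[!young] <- q_fixed(sex[!young], spec, unit = unit)
    mode[!young] <- "fixed"
  }
  list(q = q, mode = mode)
}

#' Rescale serum creatinine by a Q-value
#'
#' The dimensionless ratio SCr/Q has median 1 in a healthy population of the
#' subject's age/sex; it is the biomarker the EKFC and r-LMR equations use.
#' Units of the two inputs are reconciled before division.
#'
#' @param scr serum creatinine, strictly positive.
#' @param q Q-value, strictly positive.
#' @param scr_unit,q_unit units of `scr` and `q`.
#' @return numeric vector, SCr/Q.
#' @examples
#' rescale_creatinine(79.56, 0.90, scr_unit = "umol_l", q_unit = "mg_dl") # 1
#' @export
rescale_creatinine <- function(scr, q,
                               scr_unit = c("umol_l", "mg_dl"),
                               q_unit = c("umol_l", "mg_dl")) {
  scr_unit <- match.arg(scr_unit); q_unit <- match.arg(q_unit)
  scr_to_umol_l(scr, scr_unit) / scr_to_umol_l(q, q_unit)
}

check_age_range <- function(age, lo, hi) {
  if (any(!is.finite(age)) || any(age < lo) || any(age > hi)) {
    stop("age must lie in [", lo, ", ", hi, "] years", call. = FALSE)
  }
  invisible(age)
}
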