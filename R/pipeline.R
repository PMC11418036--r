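GFR_BIN_BREAKS <- c(-Inf, 30, 45, 60, 90, 120, Inf)
GFR_BIN_LABELS <- c("<30", "30-45", "45-60", "60-90", "90-120", ">=120")
BMI_BIN_BREAKS <- c(-Inf, 18.5, 25, 30, Inf)
BMI_BIN_LABELS <- c("<18.5", "18.5-25", "25-30", ">=30")

#' Assign subjects to strata
#'
#' Subgroup axes used in equation-validation studies: whole cohort, sex,
#' race, measured-GFR category, estimated-GFR category (per equation — the
#' bins are computed from that equation's own eGFR), or BMI category. GFR
#' bins use the usual categories <30, 30-45, 45-60, 60-90, 90-120, >=120
#' mL/min/1.73 m^2, left-closed (a value of 120 falls in ">=120"); BMI bins
#' are <18.5, 18.5-25, 25-30, >=30 kg/m^2. Missing optional fields go to an
#' explicit `"unknown"` stratum so stratum sizes always sum to the cohort
#' size.
#'
#' @param cohort cohort data frame.
#' @param by one of `"all"`, `"sex"`, `"race"`, `"mgfr_category"`,
#'   `"egfr_category"`, `"bmi_category"`.
#' @param egfr numeric vector of estimates (required for
#'   `by = "egfr_category"`).
#' @return character vector of stratum labels, length `nrow(cohort)`.
#' @export
stratify <- function(cohort, by = c("all", "sex", "race", "mgfr_category",
                                    "egfr_category", "bmi_category"),
                     egfr = NULL) {
  by <- match.arg(by)
  n <- nrow(cohort)
  lab <- switch(by,
    all = rep("all", n),
    sex = {
      if (!"sex" %in% names(cohort)) stop_axis("sex")
      as_sex(cohort$sex)
    },
    race = {
      if (!"race" %in% names(cohort)) stop_axis("race")
      as.character(cohort$race)
    },
    mgfr_category = {
      if (!"mgfr" %in% names(cohort)) stop_axis("mgfr_category", "mgfr")
      gfr_bin(cohort$mgfr)
    },
    egfr_category = {
      if (is.null(egfr)) {
        stop("egfr_category stratification needs the equation's own eGFR ",
             "values via the 'egfr' argument", call. = FALSE)
      }
      stopifnot(length(egfr) == n)
      gfr_bin(egfr)
    },
    bmi_category = {
      if (!"bmi" %in% names(cohort)) stop_axis("bmi_category", "bmi")
      as.character(cut(cohort$bmi, BMI_BIN_BREAKS, BMI_BIN_LABELS,
                       right = FALSE))
    })
  lab[is.na(lab)] <- "unknown"
  lab
}

stop_axis <- function(axis, col = axis) {
  stop("stratification axis '", axis, "' needs column '", col, "'",
       call. = FALSE)
}

gfr_bin <- function(x) {
  as.character(cut(x, GFR_BIN_BREAKS, GFR_BIN_LABELS, right = FALSE))
}

#' Read a cohort CSV
#'
#' Schema: columns `id`, `age_years`, `sex` (F/M), exactly one of
#' `scr_umol_l` / `scr_mg_dl`, optional `mgfr_ml_min_173`, `race`, `bmi` (or
#' `height_cm` + `weight_kg`, from which BMI is derived), `cohort`.
#' Malformed rows (non-numeric or non-positive creatinine/mGFR, age < 2,
#' bad sex code) are collected into the `rejects` attribute with one reason
#' per row, never silently dropped.
#'
#' @param path CSV file path.
#' @return cohort data frame (columns `id`, `age`, `sex`, `scr_umol_l`,
#'   `mgfr`, plus optional `race`/`bmi`/`cohort`), with attribute `rejects`
#'   (data frame: `row`, `id`, `reason`).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path,
                               call. = FALSE)
  # read as character: numeric fields are converted explicitly below, and a
  # sex column of all "F" must not be type-guessed into a logical
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "age_years", "sex")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("cohort file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  has_u <- "scr_umol_l" %in% names(raw); has_m <- "scr_mg_dl" %in% names(raw)
  if (has_u == has_m) {
    stop("cohort file must have exactly one of scr_umol_l / scr_mg_dl",
         call. = FALSE)
  }
  scr <- suppressWarnings(as.numeric(
    if (has_u) raw$scr_umol_l else raw$scr_mg_dl))
  if (has_m) scr <- scr * CREAT_UMOL_PER_MGDL
  age <- suppressWarnings(as.numeric(raw$age_years))
  mgfr <- if ("mgfr_ml_min_173" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$mgfr_ml_min_173))
  } else rep(NA_real_, nrow(raw))
  sex_ok <- tolower(raw$sex) %in% c("f", "m", "female", "male")
  reason <- rep(NA_character_, nrow(raw))
  reason[!sex_ok] <- "unrecognized sex code"
  reason[is.na(age) | age < 2] <- "missing or sub-pediatric age"
  reason[is.na(scr) | scr <= 0] <- "non-positive creatinine"
  reason[!is.na(mgfr) & mgfr <= 0] <- "non-positive mGFR"
  keep <- is.na(reason)
  out <- data.frame(
    id = as.character(raw$id[keep]),
    age = age[keep],
    sex = as_sex(raw$sex[keep]),
    scr_umol_l = scr[keep],
    mgfr = mgfr[keep],
    stringsAsFactors = FALSE
  )
  if ("race" %in% names(raw)) out$race <- as.character(raw$race[keep])
  if ("bmi" %in% names(raw)) {
    out$bmi <- suppressWarnings(as.numeric(raw$bmi[keep]))
  } else if (all(c("height_cm", "weight_kg") %in% names(raw))) {
    h <- suppressWarnings(as.numeric(raw$height_cm[keep])) / 100
    w <- suppressWarnings(as.numeric(raw$weight_kg[keep]))
    out$bmi <- w / h^2
  }
  if ("cohort" %in% names(raw)) out$cohort <- as.character(raw$cohort[keep])
  attr(out, "rejects") <- data.frame(
    row = which(!keep), id = as.character(raw$id[!keep]),
    reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Run the full validation pipeline
#'
#' End-to-end orchestration: obtain a cohort (from a file or a synthetic
#' profile), compute eGFR under the configured equations, build stratified
#' performance tables, pairwise CI-overlap verdicts on the whole cohort,
#' age-trend curves (median-bias quantile polynomial and P30 free-knot
#' spline), Bland-Altman summaries, and — when `q_mode_compare` is set —
#' paired EKFC/r-LMR rows under polynomial and fixed Q. Deterministic given
#' the config; the returned bundle embeds the config and package version for
#' provenance.
#'
#' @param config list with fields: one of `cohort_file` or
#'   `profile` (+ `seed`, optional `n`); `equations` (default all three);
#'   `q_population` (default the profile's, else `"europe"`); `q_mode`
#'   (`"auto"`/`"fixed"`); `strata` (axes for [stratify()], default
#'   `c("all", "sex", "mgfr_category")`); `n_boot` (default 2000); `seed`;
#'   `q_mode_compare` (logical, default TRUE); `trend_degree` (default 4).
#' @return a `validation_report` list: `cohort_n`, `performance`,
#'   `egfr_stratified`, `verdicts`, `trends`, `bland_altman`,
#'   `q_mode_comparison`, `rejects`, `provenance`.
#' @export
run_validation <- function(config) {
  config <- normalize_config(config)
  rejects <- NULL
  if (!is.null(config$cohort_file)) {
    cohort <- read_cohort_csv(config$cohort_file)
    rejects <- attr(cohort, "rejects")
    q_pop <- config$q_population %||% "europe"
  } else {
    # exact indexing: `$n` would partial-match `n_boot`
    cohort <- generate_cohort(config$profile, seed = config$seed,
                              n = config[["n"]])
    q_pop <- config$q_population %||%
      attr(cohort, "profile")$q_population
  }
  if (!"mgfr" %in% names(cohort) || all(is.na(cohort$mgfr))) {
    stop("validation needs measured GFR (mgfr) for every subject",
         call. = FALSE)
  }
  spec <- q_spec(q_pop)
  strata <- lapply(stats::setNames(config$strata, config$strata),
                   function(ax) stratify(cohort, ax))
  perf <- performance_table(cohort, equations = config$equations,
                            strata = strata, spec = spec,
                            q_mode = config$q_mode,
                            n_boot = config$n_boot, seed = config$seed)
  # eGFR-category stratification is per equation (each equation's own bins)
  egfr_strat <- list()
  if (isTRUE(config$egfr_category)) {
    for (eq in config$equations) {
      res <- egfr_batch(cohort, eq, spec = spec, q_mode = config$q_mode)
      lab <- rep("rejected", nrow(cohort))
      ok <- res$status == "ok"
      lab[ok] <- stratify(cohort[ok, , drop = FALSE], "egfr_category",
                          egfr = res$egfr[ok])
      egfr_strat[[eq]] <- performance_table(
        cohort, equations = eq,
        strata = list(egfr_category = lab), spec = spec,
        q_mode = config$q_mode, n_boot = config$n_boot, seed = config$seed)
    }
  }
  whole <- perf[perf$axis == names(strata)[1] & perf$stratum == "all", ]
  verdicts <- list()
  if (nrow(whole) >= 2) {
    pairs <- utils::combn(seq_len(nrow(whole)), 2)
    for (m in c("bias", "p30", "p20")) {
      for (j in seq_len(ncol(pairs))) {
        a <- whole[pairs[1, j], ]; b <- whole[pairs[2, j], ]
        verdicts[[length(verdicts) + 1L]] <-
          compare_by_ci_overlap(a, b, metric = m)
      }
    }
  }
  trends <- list(); ba <- list()
  for (eq in config$equations) {
    res <- egfr_batch(cohort, eq, spec = spec, q_mode = config$q_mode)
    ok <- res$status == "ok"
    if (sum(ok) < 50) next
    bias <- res$egfr[ok] - cohort$mgfr[ok]
    trends[[eq]] <- list(
      bias_curve = fit_bias_age_curve(cohort$age[ok], bias,
                                      degree = config$trend_degree),
      p30_curve = fit_p30_age_curve(
        cohort$age[ok],
        as.numeric(abs(bias) <= 0.30 * cohort$mgfr[ok])))
    ba[[eq]] <- list(
      absolute = bland_altman(res$egfr[ok], cohort$mgfr[ok], "absolute"),
      relative = bland_altman(res$egfr[ok], cohort$mgfr[ok], "relative"))
  }
  qcmp <- NULL
  if (isTRUE(config$q_mode_compare)) {
    eqs <- intersect(config$equations, c("EKFC", "r-LMR"))
    if (length(eqs)) {
      both <- lapply(c(auto = "auto", fixed = "fixed"), function(qm) {
        performance_table(cohort, equations = eqs,
                          strata = list(all = rep("all", nrow(cohort))),
                          spec = spec, q_mode = qm,
                          n_boot = config$n_boot, seed = config$seed)
      })
      both$auto$q_mode <- "polynomial"; both$fixed$q_mode <- "fixed"
      qcmp <- rbind(both$auto, both$fixed)
    }
  }
  structure(list(
    cohort_n = nrow(cohort),
    performance = perf,
    egfr_stratified = egfr_strat,
    verdicts = verdicts,
    trends = trends,
    bland_altman = ba,
    q_mode_comparison = qcmp,
    rejects = rejects,
    provenance = list(config = config,
                      package_version = as.character(
                        utils::packageVersion("gfryoung")))
  ), class = "validation_report")
}

normalize_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$cohort_file) && is.null(config$profile)) {
    stop("config needs either 'cohort_file' or 'profile'", call. = FALSE)
  }
  config$equations <- config$equations %||% c("EKFC", "CKD-EPI", "r-LMR")
  config$q_mode <- config$q_mode %||% "auto"
  config$strata <- config$strata %||% c("all", "sex", "mgfr_category")
  if (!"all" %in% config$strata) config$strata <- c("all", config$strata)
  config$n_boot <- config$n_boot %||% 2000
  config$seed <- config$seed %||% 1L
  config$trend_degree <- config$trend_degree %||% 4
  config$q_mode_compare <- config$q_mode_compare %||% TRUE
  config$egfr_category <- config$egfr_category %||% FALSE
  config
}

#' Read a run configuration from YAML
#'
#' Thin wrapper: the YAML document mirrors the `config` list of
#' [run_validation()] field for field.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  normalize_config(yaml::read_yaml(path))
}

#' Write a validation report bundle to disk
#'
#' Emits `performance.csv` (the stratified performance table),
#' `q_mode_comparison.csv` (when present), `report.json` (the full bundle:
#' verdicts, trend curves as coefficients+knots, Bland-Altman summaries,
#' provenance) and `trend_grid.csv` (plot-ready (age, fitted) pairs on the
#' evaluation range). Writing is deterministic, so repeated runs of the same
#' config diff clean.
#'
#' @param report a `validation_report` from [run_validation()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "performance.csv")
  utils::write.csv(report$performance, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$q_mode_comparison)) {
    p <- file.path(dir, "q_mode_comparison.csv")
    utils::write.csv(report$q_mode_comparison, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  grid_rows <- list()
  for (eq in names(report$trends)) {
    for (kind in names(report$trends[[eq]])) {
      curve <- report$trends[[eq]][[kind]]
      ages <- seq(curve$eval_age_range[1], curve$eval_age_range[2],
                  length.out = 101)
      grid_rows[[paste(eq, kind)]] <- data.frame(
        equation = eq, curve = kind, age = ages,
        fitted = eval_trend(curve, ages))
    }
  }
  if (length(grid_rows)) {
    p <- file.path(dir, "trend_grid.csv")
    utils::write.csv(do.call(rbind, grid_rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "report.json")
  json <- report
  json$bland_altman <- lapply(json$bland_altman, function(x) {
    lapply(x, function(b) b[setdiff(names(b), c("x", "differences"))])
  })
  json$trends <- lapply(json$trends, function(x) lapply(x, unclass))
  jsonlite::write_json(unclass(json), p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$cohort_n, "subjects\n")
  whole <- x$performance[x$performance$stratum == "all", ]
  if (nrow(whole)) {
    cat("  whole-cohort bias (95% CI) / P30:\n")
    for (i in seq_len(nrow(whole))) {
      cat(sprintf("    %-8s %6.2f (%.2f; %.2f)   P30 %.1f%%\n",
                  whole$equation[i], whole$bias[i], whole$bias_lo[i],
                  whole$bias_hi[i], whole$p30[i]))
    }
  }
  invisible(x)
}
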