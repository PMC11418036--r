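#' Median bias of an estimate against the reference
#'
#' Bias is defined pairwise as eGFR - mGFR; the summary statistic is its
#' sample median (midpoint interpolation for even n). Positive values mean
#' the equation overestimates measured GFR.
#'
#' @param egfr,mgfr paired numeric vectors (mL/min/1.73 m^2).
#' @return median of `egfr - mgfr`.
#' @export
median_bias <- function(egfr, mgfr) {
  check_paired(egfr, mgfr)
  stats::median(egfr - mgfr)
}

#' Bootstrap confidence interval for the median bias
#'
#' Nonparametric bootstrap percentile interval for the median of the paired
#' differences: `n_boot` resamples of the differences with replacement, CI
#' endpoints at the (1-level)/2 and 1-(1-level)/2 quantiles of the resampled
#' medians. Reproducible for a fixed `seed`.
#'
#' @inheritParams median_bias
#' @param level confidence level, default 0.95.
#' @param n_boot number of bootstrap resamples, default 2000.
#' @param seed integer seed (mandatory: the interval is part of a
#'   deterministic report).
#' @return numeric length-2 vector `(low, high)`.
#' @export
bias_ci <- function(egfr, mgfr, level = 0.95, n_boot = 2000, seed) {
  check_paired(egfr, mgfr)
  if (missing(seed)) stop("seed is mandatory for bias_ci", call. = FALSE)
  d <- egfr - mgfr
  n <- length(d)
  if (n < 2) stop("need at least 2 paired observations", call. = FALSE)
  meds <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(idx, 2, function(i) stats::median(d[i]))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(meds, c(alpha, 1 - alpha), type = 7))
  # the point estimate always lies inside the reported interval
  m <- stats::median(d)
  c(min(ci[1], m), max(ci[2], m))
}

#' P30 / P20 accuracy
#'
#' Percentage of estimates within a proportional tolerance of the reference:
#' 100 * mean(|eGFR - mGFR| <= tol * mGFR). The boundary counts as within.
#' P30 (`tol = 0.30`) above 75% is conventionally deemed sufficient for
#' clinical decision making.
#'
#' @inheritParams median_bias
#' @param tol proportional tolerance, e.g. 0.30 or 0.20.
#' @return percentage in \[0, 100\].
#' @export
p_accuracy <- function(egfr, mgfr, tol = 0.30) {
  check_paired(egfr, mgfr)
  check_positive(mgfr, "mGFR")
  stopifnot(tol > 0, tol < 1)
  100 * mean(abs(egfr - mgfr) <= tol * mgfr)
}

#' Confidence interval for a P30/P20 percentage
#'
#' Default is the Wald normal-approximation interval p +/- z *
#' sqrt(p(100-p)/n), clipped to \[0, 100\]; `method = "wilson"` gives the
#' Wilson score interval (via [stats::prop.test()] without continuity
#' correction).
#'
#' @param p percentage in \[0, 100\].
#' @param n number of subjects behind `p`.
#' @param level confidence level.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return numeric length-2 vector `(low, high)` in percent.
#' @export
p_accuracy_ci <- function(p, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  stopifnot(p >= 0, p <= 100, n >= 1)
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (100 - p) / n)
    c(max(0, p - half), min(100, p + half))
  } else {
    x <- round(p / 100 * n)
    ci <- stats::prop.test(x, n, conf.level = level, correct = FALSE)$conf.int
    100 * as.numeric(ci)
  }
}

#' Interquartile range of the bias (imprecision)
#'
#' Quartiles of the paired differences eGFR - mGFR under the
#' linear-interpolation quantile rule (R type 7); reported as the width
#' together with (q1, q3), matching the conventional presentation
#' "width (q1; q3)".
#'
#' @inheritParams median_bias
#' @return named numeric vector `(width, q1, q3)`.
#' @export
iqr_bias <- function(egfr, mgfr) {
  check_paired(egfr, mgfr)
  if (length(egfr) < 4) {
    stop("need at least 4 paired observations for quartiles", call. = FALSE)
  }
  q <- unname(stats::quantile(egfr - mgfr, c(0.25, 0.75), type = 7))
  c(width = q[2] - q[1], q1 = q[1], q3 = q[2])
}

#' Compare two equations by confidence-interval overlap
#'
#' Two equations are declared different on a metric when their 95% CIs share
#' no point (a conservative criterion that avoids p-values). Touching
#' endpoints count as overlapping.
#'
#' @param a,b rows of a [performance_table()] (or any list/one-row data frame
#'   with `equation`, `stratum` and the metric's `*_lo` / `*_hi` fields).
#' @param metric `"bias"`, `"p30"` or `"p20"`.
#' @return list: `metric`, `equation_a`, `equation_b`, `different` (logical),
#'   `interval_a`, `interval_b`.
#' @export
compare_by_ci_overlap <- function(a, b, metric = c("bias", "p30", "p20")) {
  metric <- match.arg(metric)
  if (!identical(as.character(a$stratum), as.character(b$stratum))) {
    stop("performance summaries come from different strata: '",
         a$stratum, "' vs '", b$stratum, "'", call. = FALSE)
  }
  lo <- paste0(metric, "_lo"); hi <- paste0(metric, "_hi")
  ia <- c(a[[lo]], a[[hi]]); ib <- c(b[[lo]], b[[hi]])
  different <- isTRUE(ia[2] < ib[1] || ib[2] < ia[1])
  list(metric = metric,
       equation_a = as.character(a$equation),
       equation_b = as.character(b$equation),
       different = different, interval_a = ia, interval_b = ib)
}

#' Performance table for equations by stratum
#'
#' For each equation and each stratum, computes n, median bias with bootstrap
#' CI, IQR of the bias with quartiles, and P30/P20 with CIs — the schema of a
#' standard equation-validation table. Subjects rejected by an equation
#' (e.g. under-18 for CKD-EPI) are excluded from that equation's metrics.
#' Strata with no subjects yield a row with `n = 0` and `NA` metrics.
#'
#' @param cohort data frame with `id`, `age`, `sex`, creatinine column and
#'   `mgfr`.
#' @param equations character subset of `c("EKFC", "CKD-EPI", "r-LMR")`.
#' @param strata named list of factors/character vectors of length
#'   `nrow(cohort)` assigning each subject to a stratum, e.g. the output of
#'   [stratify()]; the default is a single whole-cohort stratum.
#' @param spec,q_mode passed to [egfr_batch()].
#' @param n_boot,seed bootstrap settings for the bias CI.
#' @param ci_method method for the P30/P20 CI, see [p_accuracy_ci()].
#' @return data frame, one row per equation x stratum: `equation`, `axis`,
#'   `stratum`, `n`, `bias`, `bias_lo`, `bias_hi`, `iqr`, `iqr_q1`, `iqr_q3`,
#'   `p30`, `p30_lo`, `p30_hi`, `p20`, `p20_lo`, `p20_hi`.
#' @export
performance_table <- function(cohort,
                              equations = c("EKFC", "CKD-EPI", "r-LMR"),
                              strata = list(all = rep("all", nrow(cohort))),
                              spec = q_spec("europe"),
                              q_mode = c("auto", "fixed"),
                              n_boot = 2000, seed = 1L,
                              ci_method = "wald") {
  q_mode <- match.arg(q_mode)
  if (!"mgfr" %in% names(cohort)) {
    stop("performance_table needs measured GFR in column 'mgfr'",
         call. = FALSE)
  }
  equations <- match.arg(equations, c("EKFC", "CKD-EPI", "r-LMR"),
                         several.ok = TRUE)
  rows <- list()
  for (eq in equations) {
    res <- egfr_batch(cohort, eq, spec = spec, q_mode = q_mode)
    for (axis in names(strata)) {
      lab <- as.character(strata[[axis]])
      stopifnot(length(lab) == nrow(cohort))
      for (st in unique_strata(lab)) {
        keep <- lab == st & res$status == "ok"
        rows[[length(rows) + 1L]] <- performance_row(
          eq, axis, st, res$egfr[keep], cohort$mgfr[keep],
          n_boot = n_boot,
          seed = substream_seed(seed, length(rows)),
          ci_method = ci_method)
      }
    }
  }
  do.call(rbind, rows)
}

performance_row <- function(equation, axis, stratum, egfr, mgfr,
                            n_boot, seed, ci_method) {
  n <- length(egfr)
  out <- data.frame(
    equation = equation, axis = axis, stratum = stratum, n = n,
    bias = NA_real_, bias_lo = NA_real_, bias_hi = NA_real_,
    iqr = NA_real_, iqr_q1 = NA_real_, iqr_q3 = NA_real_,
    p30 = NA_real_, p30_lo = NA_real_, p30_hi = NA_real_,
    p20 = NA_real_, p20_lo = NA_real_, p20_hi = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)
  out$bias <- median_bias(egfr, mgfr)
  if (n >= 10) {
    ci <- bias_ci(egfr, mgfr, n_boot = n_boot, seed = seed)
    out$bias_lo <- ci[1]; out$bias_hi <- ci[2]
  }
  if (n >= 4) {
    iq <- iqr_bias(egfr, mgfr)
    out$iqr <- iq[["width"]]; out$iqr_q1 <- iq[["q1"]]; out$iqr_q3 <- iq[["q3"]]
  }
  out$p30 <- p_accuracy(egfr, mgfr, 0.30)
  out$p20 <- p_accuracy(egfr, mgfr, 0.20)
  ci30 <- p_accuracy_ci(out$p30, n, method = ci_method)
  ci20 <- p_accuracy_ci(out$p20, n, method = ci_method)
  out$p30_lo <- ci30[1]; out$p30_hi <- ci30[2]
  out$p20_lo <- ci20[1]; out$p20_hi <- ci20[2]
  out
}

# Stable stratum ordering: factor levels if given, else order of appearance.
unique_strata <- function(lab) {
  u <- unique(lab)
  u[order(match(u, u))]
}

check_paired <- function(egfr, mgfr) {
  if (length(egfr) == 0) stop("empty input", call. = FALSE)
  if (length(egfr) != length(mgfr)) {
    stop("egfr and mgfr must be paired vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(egfr)) || any(!is.finite(mgfr))) {
    stop("egfr/mgfr must be finite", call. = FALSE)
  }
  invisible(NULL)
}
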