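#' Creatinine unit conversion
#'
#' Serum creatinine is handled internally in umol/L (the unit of the Q-value
#' age polynomials). The conversion factor between units is
#' 1 mg/dL = 88.4 umol/L. Conversions are exact divisions/multiplications and
#' round-trip stable.
#'
#' @param x numeric vector of concentrations, strictly positive.
#' @param unit unit of `x`: `"umol_l"` or `"mg_dl"`.
#' @return numeric vector in the requested unit.
#' @examples
#' scr_to_umol_l(0.90, "mg_dl")   # 79.56
#' scr_to_mg_dl(79.56, "umol_l")  # 0.90
#' @export
scr_to_umol_l <- function(x, unit = c("umol_l", "mg_dl")) {
  unit <- match.arg(unit)
  check_positive(x, "creatinine concentration")
  if (unit == "mg_dl") x * CREAT_UMOL_PER_MGDL else x
}

#' @rdname scr_to_umol_l
#' @export
scr_to_mg_dl <- function(x, unit = c("umol_l", "mg_dl")) {
  unit <- match.arg(unit)
  check_positive(x, "creatinine concentration")
  if (unit == "umol_l") x / CREAT_UMOL_PER_MGDL else x
}

# umol/L per mg/dL for creatinine (molar mass 113.12 g/mol; clinical constant)
CREAT_UMOL_PER_MGDL <- 88.4

check_positive <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be finite and strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' Normalize a sex vector to the two-level factor used throughout
#'
#' Accepts `"female"`/`"male"`, `"F"`/`"M"` (any case). All Q-value and
#' equation dispatch is total over the two levels.
#'
#' @param sex character or factor vector.
#' @return character vector with values `"female"`/`"male"`.
#' @export
as_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female")] <- "female"
  s[s %in% c("m", "male")] <- "male"
  bad <- !s %in% c("female", "male")
  if (any(bad)) {
    stop("sex must be 'female'/'male' (or 'F'/'M'); got: ",
         paste(unique(sex[bad]), collapse = ", "), call. = FALSE)
  }
  s
}
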