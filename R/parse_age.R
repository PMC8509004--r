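#' Parse BrainSpan-style age strings to years
#'
#' The atlas records donor age as free text: \code{"<n> pcw"} (post-conception
#' weeks, prenatal), \code{"<n> mos"} (postnatal months) or \code{"<n> yrs"}
#' (postnatal years). Postnatal ages are converted to continuous years
#' (months / 12, full precision retained; the conventional display value 0.33
#' for 4 months is a rounding of 1/3). Prenatal \code{"pcw"} records map to
#' \code{NA}, the marker downstream loaders use to exclude them — the screen
#' models the postnatal lifespan only.
#'
#' @param x Character vector of age strings.
#' @return Numeric vector of ages in years; \code{NA} marks prenatal records.
#'   Unrecognised strings raise an error naming the offender.
#' @export
#' @examples
#' parse_age(c("4 mos", "12 mos", "3 yrs"))   # 0.333..., 1, 3
#' parse_age("37 pcw")                        # NA (prenatal)
parse_age <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]+)\\s*(pcw|mos|yrs)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unrecognised age string(s): ",
         paste(sQuote(x[bad]), collapse = ", "))
  }
  n    <- as.numeric(vapply(m, `[`, "", 2L))
  unit <- vapply(m, `[`, "", 3L)
  out <- rep(NA_real_, length(x))
  out[unit == "mos"] <- n[unit == "mos"] / 12
  out[unit == "yrs"] <- n[unit == "yrs"]
  out  # pcw stays NA: prenatal marker
}

#' Serialise ages in years back to the atlas dialect
#'
#' Inverse of [parse_age()] up to month resolution: ages are written as the
#' nearest representable \code{"N mos"} or \code{"N yrs"} string (whole years
#' from 1 upward serialise as years, everything else as months).
#'
#' @param age_years Numeric vector of postnatal ages in years.
#' @return Character vector of dialect age strings.
#' @export
#' @examples
#' format_age(c(1 / 3, 1, 40))  # "4 mos" "1 yrs" "40 yrs"
format_age <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years > 0))
  months <- round(age_years * 12)
  ifelse(months %% 12 == 0,
         paste(months %/% 12, "yrs"),
         paste(months, "mos"))
}
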