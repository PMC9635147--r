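#' ICS daily-dose banding
#'
#' The BTS/SIGN guideline tables give a single recommended daily dose for each
#' of the low, medium and high levels of an ICS product; observed prescribed
#' daily doses rarely sit exactly on those values, so each level is widened to
#' a range. [derive_band_ranges()] builds the ranges from the per-product
#' threshold triple and [classify_daily_dose()] assigns a dose to
#' LOW / MEDIUM / HIGH / UNKNOWN.
#'
#' @name dose_banding
NULL

band_levels <- c("NONE", "LOW", "MEDIUM", "HIGH", "UNKNOWN")

#' Derive dose-band ranges from guideline threshold values
#'
#' Ranges are constructed at one-microgram granularity: low runs from zero up
#' to the low-dose value; medium from one microgram above the low-dose value
#' up to the medium-dose value, or from half the medium-dose value when no
#' low dose is recommended; high from one microgram above the medium-dose
#' value up to four times the medium-dose value, or, when no medium dose is
#' recommended, from half the high-dose value up to twice the high-dose
#' value. Doses above the high upper limit are later classified 'unknown'.
#'
#' @param band_low,band_medium recommended daily doses (mcg/day), `NA` when
#'   the guideline lists no such level for the product.
#' @param band_high recommended high daily dose (mcg/day); required.
#' @return list with elements `low_upper`, `medium_lower`, `medium_upper`,
#'   `high_lower`, `high_upper` (`NA` where the level is absent).
#' @export
#' @examples
#' derive_band_ranges(400, 800, 2000)
derive_band_ranges <- function(band_low, band_medium, band_high) {
  if (is.na(band_high)) {
    stop("band_high is required for every ICS product")
  }
  thr <- c(band_low, band_medium, band_high)
  if (any(diff(thr[!is.na(thr)]) <= 0)) {
    stop("band thresholds must be strictly increasing")
  }
  if (!is.na(band_medium)) {
    medium_lower <- if (!is.na(band_low)) band_low + 1 else band_medium / 2
    medium_upper <- band_medium
    high_lower <- band_medium + 1
    high_upper <- 4 * band_medium
  } else {
    medium_lower <- NA_real_
    medium_upper <- NA_real_
    high_lower <- band_high / 2
    high_upper <- 2 * band_high
  }
  list(
    low_upper = if (!is.na(band_low)) band_low else NA_real_,
    medium_lower = medium_lower,
    medium_upper = medium_upper,
    high_lower = high_lower,
    high_upper = high_upper
  )
}

#' Classify a prescribed daily ICS dose into a band
#'
#' Classification is sequential on the upper limits, which keeps the mapping
#' total even when a product has no recommended low or medium level (the
#' guideline construction then leaves a gap between the stated ranges; doses
#' in such a gap are assigned to the band below the next stated lower limit).
#' Fractional daily doses are rounded half-up to the nearest microgram before
#' comparison, matching the one-microgram boundary construction.
#'
#' @param dose prescribed daily dose, mcg/day, strictly positive.
#' @param ranges list from [derive_band_ranges()].
#' @return one of `"LOW"`, `"MEDIUM"`, `"HIGH"`, `"UNKNOWN"`.
#' @export
#' @examples
#' r <- derive_band_ranges(400, 800, 2000)
#' classify_daily_dose(400, r)   # LOW (boundary inclusive)
#' classify_daily_dose(401, r)   # MEDIUM
#' classify_daily_dose(3201, r)  # UNKNOWN
classify_daily_dose <- function(dose, ranges) {
  if (is.na(dose) || dose <= 0) stop("dose must be a positive number of mcg/day")
  dose <- floor(dose + 0.5)
  low_upper <- ranges$low_upper
  if (is.na(low_upper)) {
    low_upper <- if (!is.na(ranges$medium_lower)) ranges$medium_lower - 1 else ranges$high_lower - 1
  }
  medium_upper <- ranges$medium_upper
  if (is.na(medium_upper)) medium_upper <- ranges$high_lower - 1
  if (dose <= low_upper) return("LOW")
  if (dose <= medium_upper) return("MEDIUM")
  if (dose <= ranges$high_upper) return("HIGH")
  "UNKNOWN"
}

# vectorised banding against catalogue threshold columns
band_daily_dose_vec <- function(dose, band_low, band_medium, band_high) {
  out <- character(length(dose))
  for (i in seq_along(dose)) {
    out[i] <- classify_daily_dose(dose[i],
                                  derive_band_ranges(band_low[i], band_medium[i], band_high[i]))
  }
  out
}
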