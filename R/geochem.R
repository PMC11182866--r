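#' Atomic TC:TN ratio
#'
#' Converts mass percentages of total carbon and total nitrogen into the
#' atomic (molar) C:N ratio, `(TC/12.011) / (TN/14.007)`. Ratios above ~20
#' indicate vascular-plant organic matter; 5-8 indicates plankton dominance,
#' so declining ratios track shifts toward phytoplankton-derived sediment.
#'
#' @param tc_percent total carbon (mass %).
#' @param tn_percent total nitrogen (mass %), > 0.
#' @return Unitless atomic ratio.
#' @examples
#' atomic_cn(4.8, 0.56)  # ~10.0
#' @export
atomic_cn <- function(tc_percent, tn_percent) {
  if (any(tn_percent <= 0))
    stop("`tn_percent` must be > 0", call. = FALSE)
  (tc_percent / 12.011) / (tn_percent / 14.007)
}

#' Approximate atmospheric delta13C history for Suess correction
#'
#' A packaged default reference curve for the industrial-era decline of
#' atmospheric CO2 delta13C (the Suess effect): approximately -6.4 permil in
#' the preindustrial atmosphere, falling slowly to about -6.7 permil by 1920
#' and then increasingly steeply to about -8.4 permil by 2018. The table is
#' an approximate synthetic reconstruction assembled from widely reported
#' magnitudes of the atmospheric record, adequate for testing and synthetic
#' work; for research use supply a published curve via the `curve` argument
#' of [suess_correct()].
#'
#' @return Data frame `year_ce`, `d13c_atm_permil` at decadal resolution
#'   (1850-2030), suitable for linear interpolation.
#' @export
default_suess_curve <- function() {
  data.frame(
    year_ce = seq(1850, 2030, by = 10),
    d13c_atm_permil = c(-6.41, -6.43, -6.46, -6.49, -6.53, -6.57, -6.62,
                        -6.67, -6.73, -6.80, -6.88, -6.97, -7.08, -7.22,
                        -7.40, -7.62, -7.87, -8.13, -8.40)
  )
}

#' Suess-effect correction of sedimentary delta13C
#'
#' Removes the industrial-era atmospheric CO2 delta13C decline from a
#' measured sedimentary value so that residual trends reflect in-lake
#' processes: `corrected = measured - (d13c_atm(year) - d13c_atm(ref_year))`,
#' with the atmospheric curve evaluated by linear interpolation between
#' tabulated years.
#'
#' @param d13c_measured measured delta13C (permil vs V-PDB).
#' @param year calendar year (CE) of the sample; must lie within the curve.
#' @param curve reference curve data frame (`year_ce`, `d13c_atm_permil`);
#'   defaults to [default_suess_curve()].
#' @param ref_year reference year the record is corrected to (default 1900,
#'   the start of the reconstructed span).
#' @return Corrected delta13C (permil).
#' @examples
#' crv <- data.frame(year_ce = c(1900, 2000), d13c_atm_permil = c(-6.5, -8.0))
#' suess_correct(-24, 1950, crv, ref_year = 1900)  # -23.25
#' @export
suess_correct <- function(d13c_measured, year, curve = default_suess_curve(),
                          ref_year = 1900) {
  check_increasing(curve$year_ce, "curve$year_ce")
  span <- range(curve$year_ce)
  if (any(year < span[1] | year > span[2]) ||
      ref_year < span[1] || ref_year > span[2])
    stop("year outside the span of the atmospheric reference curve",
         call. = FALSE)
  atm <- function(y) stats::approx(curve$year_ce, curve$d13c_atm_permil,
                                   xout = y)$y
  d13c_measured - (atm(year) - atm(ref_year))
}
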