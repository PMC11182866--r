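#' Controlled vocabulary of taxonomically diagnostic sedimentary pigments
#'
#' The pigments quantified by the pipeline together with their taxonomic
#' affiliation (all primary producers, cryptophytes, diatoms,
#' dinoflagellates/chrysophytes, chlorophytes, cyanobacteria).
#'
#' @return Data frame with columns `pigment` and `affiliation`.
#' @export
pigment_vocabulary <- function() {
  data.frame(
    pigment = c("beta,beta-carotene", "chlorophyll a", "pheophytin a",
                "pheophorbide a", "alloxanthin", "diatoxanthin",
                "diadinoxanthin", "dinoxanthin", "peridinin", "lutein",
                "echinenone", "canthaxanthin", "myxoxanthophyll",
                "oscillaxanthin", "zeaxanthin"),
    affiliation = c("all primary producers", "all primary producers",
                    "chlorophyll a derivative", "chlorophyll a derivative",
                    "cryptophytes", "diatoms",
                    "diatoms, dinoflagellates, chrysophytes",
                    "dinoflagellates & chrysophytes", "dinoflagellates",
                    "chlorophytes", "total cyanobacteria",
                    "colonial cyanobacteria", "cyanobacteria",
                    "cyanobacteria (Oscillatoria)", "cyanobacteria"),
    stringsAsFactors = FALSE
  )
}

check_pigment_names <- function(pigment) {
  bad <- setdiff(unique(pigment), pigment_vocabulary()$pigment)
  if (length(bad))
    warning("pigment name(s) outside the controlled vocabulary: ",
            paste(bad, collapse = ", "), call. = FALSE)
  invisible(pigment)
}

#' Normalize a pigment concentration to organic carbon
#'
#' Converts nmol per g dry sediment to nmol per g organic carbon by dividing
#' by the organic-carbon mass fraction (total carbon is assumed fully
#' organic, as in carbonate-free sediments).
#'
#' @param conc_per_g_dry concentration (nmol/g dry sediment), >= 0.
#' @param tc_percent total (organic) carbon content in percent, in (0, 100].
#' @return Concentration in nmol per g organic carbon.
#' @examples
#' normalize_to_oc(10, 5)  # 200
#' @export
normalize_to_oc <- function(conc_per_g_dry, tc_percent) {
  if (any(tc_percent <= 0 | tc_percent > 100))
    stop("`tc_percent` must lie in (0, 100]", call. = FALSE)
  conc_per_g_dry / (tc_percent / 100)
}

#' Chlorophyll preservation index (CPI)
#'
#' The ratio of chlorophyll a to the sum of chlorophyll a and its measured
#' degradation products (pheophytin a and pheophorbide a). Values near 1
#' indicate fresh, well-preserved pigment; values near 0 indicate heavy
#' degradation, typical of warm productive lakes.
#'
#' @param chl_a,pheophytin_a,pheophorbide_a concentrations, all >= 0 and in
#'   the same units.
#' @return Index in [0, 1]; `NA` (flagged by warning) when all three are 0.
#' @export
cpi <- function(chl_a, pheophytin_a, pheophorbide_a) {
  if (any(c(chl_a, pheophytin_a, pheophorbide_a) < 0, na.rm = TRUE))
    stop("pigment concentrations must be >= 0", call. = FALSE)
  total <- chl_a + pheophytin_a + pheophorbide_a
  out <- ifelse(total > 0, chl_a / total, NA_real_)
  if (anyNA(out))
    warning("CPI undefined where chlorophyll a and both derivatives are all zero",
            call. = FALSE)
  out
}

#' Pigment flux (accumulation rate)
#'
#' Converts a concentration per g dry sediment into a deposition rate per
#' unit area and time: `concentration * dry bulk density * sedimentation
#' rate` (nmol/cm^2/yr).
#'
#' @param conc_per_g_dry concentration (nmol/g dry sediment).
#' @param dry_bulk_density_g_cm3 dry bulk density (g/cm^3), > 0.
#' @param sed_rate_cm_yr sedimentation rate (cm/yr), > 0.
#' @return Flux in nmol/cm^2/yr.
#' @examples
#' pigment_flux(100, 0.5, 0.2)  # 10
#' @export
pigment_flux <- function(conc_per_g_dry, dry_bulk_density_g_cm3,
                         sed_rate_cm_yr) {
  if (any(dry_bulk_density_g_cm3 <= 0) || any(sed_rate_cm_yr <= 0))
    stop("density and sedimentation rate must be > 0", call. = FALSE)
  conc_per_g_dry * dry_bulk_density_g_cm3 * sed_rate_cm_yr
}

#' Process a long pigment table into OC-normalized series with CPI
#'
#' Joins a long pigment table (depth, pigment, concentration per g dry
#' sediment) with total-carbon measurements, normalizes every concentration
#' to organic carbon, and computes the per-depth chlorophyll preservation
#' index.
#'
#' @param pigments data frame `depth_cm`, `pigment`, `conc`, `units`
#'   (`"nmol_g_ds"` or `"nmol_g_oc"`).
#' @param geochem data frame with `depth_cm` and `tc_pct` used for the
#'   normalization (matched by nearest depth).
#' @return A list with `normalized` (long table, nmol/g OC) and `cpi`
#'   (per-depth data frame `depth_cm`, `cpi`).
#' @export
process_pigments <- function(pigments, geochem) {
  check_pigment_names(pigments$pigment)
  tc <- geochem$tc_pct[vapply(pigments$depth_cm, function(d)
    which.min(abs(geochem$depth_cm - d)), integer(1))]
  out <- pigments
  needs <- out$units == "nmol_g_ds"
  out$conc[needs] <- normalize_to_oc(out$conc[needs], tc[needs])
  out$units <- "nmol_g_oc"
  wide <- function(p) {
    s <- out[out$pigment == p, c("depth_cm", "conc")]
    s$conc[match(sort(unique(out$depth_cm)), s$depth_cm)]
  }
  depths <- sort(unique(out$depth_cm))
  g <- function(p) { v <- wide(p); ifelse(is.na(v), 0, v) }
  cpi_df <- data.frame(depth_cm = depths,
                       cpi = cpi(g("chlorophyll a"), g("pheophytin a"),
                                 g("pheophorbide a")))
  list(normalized = out, cpi = cpi_df)
}
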