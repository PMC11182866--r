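#' Default body-part multiplicities per individual
#'
#' How many of each body part one individual carries: paired parts
#' (carapace valves, Chaoborus mandibles) count 2, unpaired parts
#' (headshields, postabdomens) count 1. User tables may override or extend
#' these values.
#'
#' @return Named integer vector, names are body-part labels.
#' @export
default_part_multiplicities <- function() {
  c(headshield = 1L, carapace = 2L, postabdomen = 1L, mandible = 2L)
}

#' Minimum number of individuals (MNI) from body-part counts
#'
#' For each body part, the implied number of individuals is
#' `ceiling(count / parts_per_individual)`; the MNI for the taxon is the
#' maximum over its body parts, i.e. the most abundant part after adjusting
#' for how many of it each individual carries (so 18 paired carapace valves
#' imply 9 individuals, not 18).
#'
#' @param part_counts named non-negative integer vector of counts per body
#'   part.
#' @param parts_per_individual named multiplicities; defaults to
#'   [default_part_multiplicities()]. Every counted part must have a
#'   multiplicity.
#' @return Integer MNI.
#' @examples
#' mni(c(headshield = 12, carapace = 18))  # 12
#' @export
mni <- function(part_counts, parts_per_individual = default_part_multiplicities()) {
  if (!length(part_counts)) stop("no body parts recorded", call. = FALSE)
  if (any(part_counts < 0) || any(part_counts != round(part_counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  missing_mult <- setdiff(names(part_counts), names(parts_per_individual))
  if (length(missing_mult))
    stop("no multiplicity for body part(s): ",
         paste(missing_mult, collapse = ", "), call. = FALSE)
  per_part <- ceiling(part_counts / parts_per_individual[names(part_counts)])
  as.integer(max(per_part))
}

#' Volume of sediment actually screened, from marker-spore recovery
#'
#' A known number of Lycopodium marker spores is added to each subsample;
#' the fraction of them encountered during counting estimates the fraction
#' of the subsample examined, so the screened volume is
#' `sample_volume * spores_counted / spores_added`.
#'
#' @param sample_volume_cm3 total wet subsample volume (cm^3), > 0.
#' @param spores_counted marker spores encountered (>= 0).
#' @param spores_added marker spores added (> 0).
#' @return Screened volume (cm^3). Zero spores counted give volume 0 with a
#'   warning (downstream concentrations are then undefined).
#' @examples
#' volume_screened(2, 4833, 9666)  # 1.0
#' @export
volume_screened <- function(sample_volume_cm3, spores_counted, spores_added) {
  if (any(spores_added <= 0)) stop("`spores_added` must be > 0", call. = FALSE)
  if (any(sample_volume_cm3 <= 0)) stop("volume must be > 0", call. = FALSE)
  if (any(spores_counted > spores_added))
    warning("more spores counted than added; tallies implausible",
            call. = FALSE)
  if (any(spores_counted == 0))
    warning("zero marker spores counted: screened volume 0, concentration undefined",
            call. = FALSE)
  sample_volume_cm3 * spores_counted / spores_added
}

#' Subfossil concentrations and influx from a body-part count table
#'
#' Applies the MNI rule per depth and taxon, converts to concentration
#' (individuals per cm^3 of wet sediment) using the marker-spore screened
#' volume, and to influx (individuals per cm^2 per yr) by dividing the
#' concentration by the local years-per-cm of the age model (the reciprocal
#' of its sedimentation rate at the sample depth).
#'
#' @param counts data frame `depth_cm`, `taxon`, `body_part`, `count`,
#'   `sample_volume_cm3`, `spores_counted`, `spores_added`.
#' @param age_model optional `age_model` providing `sed_rate_cm_yr`;
#'   without it influx is `NA`.
#' @param parts_per_individual multiplicity table, see [mni()].
#' @return Data frame `depth_cm`, `taxon`, `mni`, `volume_screened_cm3`,
#'   `conc_ind_cm3`, `influx_ind_cm2_yr`.
#' @export
subfossil_abundance <- function(counts, age_model = NULL,
                                parts_per_individual = default_part_multiplicities()) {
  key <- interaction(counts$depth_cm, counts$taxon, drop = TRUE)
  rows <- lapply(split(counts, key), function(g) {
    pc <- stats::setNames(g$count, g$body_part)
    vol <- volume_screened(g$sample_volume_cm3[1], g$spores_counted[1],
                           g$spores_added[1])
    data.frame(depth_cm = g$depth_cm[1], taxon = g$taxon[1],
               mni = mni(pc, parts_per_individual),
               volume_screened_cm3 = vol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$taxon, out$depth_cm), ]
  out$conc_ind_cm3 <- ifelse(out$volume_screened_cm3 > 0,
                             out$mni / out$volume_screened_cm3, NA_real_)
  if (!is.null(age_model)) {
    sr <- stats::approx(age_model$depth_cm, age_model$sed_rate_cm_yr,
                        xout = out$depth_cm, rule = 2)$y
    out$influx_ind_cm2_yr <- out$conc_ind_cm3 * sr  # conc / (yr per cm)
  } else {
    out$influx_ind_cm2_yr <- NA_real_
  }
  rownames(out) <- NULL
  out
}
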