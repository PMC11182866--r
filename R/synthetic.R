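#' Configuration for the synthetic multiproxy core generator
#'
#' Bundles every knob of the synthetic sediment-core generator into a
#' validated list. The defaults emulate a ~37 cm tropical inshore gravity
#' core collected in 2018 CE spanning back past 1900 CE: exponentially
#' decaying unsupported 210Pb over a constant supported baseline, a step-ramp
#' increase of all photosynthetic pigments at the 1920 eutrophication onset,
#' a collapse of cladoceran subfossil counts around 1957, Lycopodium marker
#' spores drawn from N(9666, 671^2), and reflectance spectra whose 655-680 nm
#' absorption trough deepens with the chloropigment sum.
#'
#' @param seed integer seed; a fixed seed makes [generate_core()] fully
#'   deterministic.
#' @param core_length_cm core length (cm).
#' @param sample_thickness_cm contiguous subsample thickness (cm).
#' @param surface_year collection year (CE) assigned to the sediment surface.
#' @param sed_rate_cm_yr constant sedimentation rate (cm/yr). The default
#'   0.21 places ~25 cm near 1900 CE.
#' @param dry_bulk_density_g_cm3 dry bulk density (g/cm^3).
#' @param pb210_flux unsupported 210Pb activity at the surface (Bq/kg).
#' @param supported_pb210 supported 210Pb baseline (Bq/kg).
#' @param activity_cv relative (1-sigma) measurement noise on activities.
#' @param intervention_year eutrophication onset (CE); pigments rise here.
#' @param collapse_year cladoceran collapse year (CE).
#' @param pigment_fold_change multiplier applied to every pigment after the
#'   intervention (the planted effect size; 2-10 is the plausible range).
#' @param cladoceran_decline_frac fractional decline of cladoceran counts
#'   after `collapse_year` (0.60-0.85 is the plausible range).
#' @param spore_mean,spore_sd marker-spore batch mean and SD per subsample.
#' @param spore_count_fraction expected proportion of added spores
#'   encountered while screening each subsample.
#' @param sample_volume_cm3 wet subsample volume (cm^3).
#' @param spectra_noise_sd additive reflectance noise (reflectance units).
#' @param pigment_noise_sdlog lognormal noise SD (log scale) on pigment
#'   concentrations.
#' @param geochem_noise_sd additive noise SD on bulk-geochemistry series.
#' @param transition_samples width of the linear pigment rise, in samples;
#'   0 gives a pure step at the intervention.
#' @param cyano_second_rise if TRUE, cyanobacteria-affiliated pigments get a
#'   second multiplier at `cyano_rise_year` (emulating a late shift to
#'   cyanobacterial dominance).
#' @param cyano_rise_year,cyano_fold timing and size of that second rise.
#' @param ar1_rho AR(1) coefficient for pigment noise (0 = independent).
#'   Provided to demonstrate that serial correlation violates the
#'   exchangeability assumption of the intervention test.
#'
#' @return A list of class `"synthetic_config"`.
#' @seealso [generate_core()], [truth_report()]
#' @export
synthetic_config <- function(seed = 1L,
                             core_length_cm = 37,
                             sample_thickness_cm = 1,
                             surface_year = 2018,
                             sed_rate_cm_yr = 0.21,
                             dry_bulk_density_g_cm3 = 0.3,
                             pb210_flux = 100,
                             supported_pb210 = 30,
                             activity_cv = 0.05,
                             intervention_year = 1920,
                             collapse_year = 1957,
                             pigment_fold_change = 5,
                             cladoceran_decline_frac = 0.75,
                             spore_mean = 9666,
                             spore_sd = 671,
                             spore_count_fraction = 0.5,
                             sample_volume_cm3 = 2,
                             spectra_noise_sd = 0.002,
                             pigment_noise_sdlog = 0.2,
                             geochem_noise_sd = 0.05,
                             transition_samples = 3L,
                             cyano_second_rise = FALSE,
                             cyano_rise_year = 1990,
                             cyano_fold = 3,
                             ar1_rho = 0) {
  cfg <- list(
    seed = as.integer(seed),
    core_length_cm = core_length_cm,
    sample_thickness_cm = sample_thickness_cm,
    surface_year = surface_year,
    sed_rate_cm_yr = sed_rate_cm_yr,
    dry_bulk_density_g_cm3 = dry_bulk_density_g_cm3,
    pb210_flux = pb210_flux,
    supported_pb210 = supported_pb210,
    activity_cv = activity_cv,
    intervention_year = intervention_year,
    collapse_year = collapse_year,
    pigment_fold_change = pigment_fold_change,
    cladoceran_decline_frac = cladoceran_decline_frac,
    spore_mean = spore_mean,
    spore_sd = spore_sd,
    spore_count_fraction = spore_count_fraction,
    sample_volume_cm3 = sample_volume_cm3,
    spectra_noise_sd = spectra_noise_sd,
    pigment_noise_sdlog = pigment_noise_sdlog,
    geochem_noise_sd = geochem_noise_sd,
    transition_samples = as.integer(transition_samples),
    cyano_second_rise = isTRUE(cyano_second_rise),
    cyano_rise_year = cyano_rise_year,
    cyano_fold = cyano_fold,
    ar1_rho = ar1_rho
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  for (nm in c("core_length_cm", "sample_thickness_cm", "sed_rate_cm_yr",
               "dry_bulk_density_g_cm3", "pb210_flux", "sample_volume_cm3",
               "spore_mean", "spore_sd"))
    stopifnot_scalar(cfg[[nm]], nm, positive = TRUE)
  for (nm in c("supported_pb210", "activity_cv", "spectra_noise_sd",
               "pigment_noise_sdlog", "geochem_noise_sd"))
    stopifnot_scalar(cfg[[nm]], nm)
  if (cfg$intervention_year >= cfg$surface_year)
    stop("`intervention_year` must precede `surface_year`", call. = FALSE)
  bottom_age <- cfg$surface_year - cfg$core_length_cm / cfg$sed_rate_cm_yr
  if (cfg$intervention_year <= bottom_age || cfg$collapse_year <= bottom_age)
    stop("intervention/collapse year falls outside the core's age span",
         call. = FALSE)
  if (cfg$cladoceran_decline_frac <= 0 || cfg$cladoceran_decline_frac >= 1)
    stop("`cladoceran_decline_frac` must lie in (0, 1)", call. = FALSE)
  if (cfg$pigment_fold_change <= 0)
    stop("`pigment_fold_change` must be > 0", call. = FALSE)
  if (cfg$spore_count_fraction <= 0 || cfg$spore_count_fraction > 1)
    stop("`spore_count_fraction` must lie in (0, 1]", call. = FALSE)
  if (abs(cfg$ar1_rho) >= 1)
    stop("`ar1_rho` must lie in (-1, 1)", call. = FALSE)
  if (cfg$transition_samples < 0)
    stop("`transition_samples` must be >= 0", call. = FALSE)
  invisible(cfg)
}

# baseline concentrations (nmol per g dry sediment) for the diagnostic
# pigment table; chlorophyll a is kept well below the summed derivatives so
# the preservation index stays < 0.1, as typical of warm eutrophic sediments
pigment_baselines <- function() {
  c(`beta,beta-carotene` = 8,
    `chlorophyll a` = 15,
    `pheophytin a` = 70,
    `pheophorbide a` = 120,
    alloxanthin = 6,
    diatoxanthin = 25,
    diadinoxanthin = 18,
    dinoxanthin = 4,
    peridinin = 3,
    lutein = 10,
    echinenone = 12,
    canthaxanthin = 9,
    myxoxanthophyll = 5,
    oscillaxanthin = 4,
    zeaxanthin = 14)
}

cyano_pigments <- function() {
  c("echinenone", "canthaxanthin", "myxoxanthophyll", "oscillaxanthin",
    "zeaxanthin")
}

# per-taxon baseline body-part count means (pre-collapse)
subfossil_baselines <- function() {
  data.frame(
    taxon = c("Alona", "Alona", "Chydorus", "Chydorus",
              "Bosmina", "Bosmina", "Chaoborus"),
    body_part = c("headshield", "carapace", "headshield", "carapace",
                  "headshield", "carapace", "mandible"),
    mean_count = c(40, 60, 30, 50, 50, 70, 0.4),
    declines = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# pigment multiplier per sample: 1 pre-intervention, linear ramp of
# `width` samples, then `fold`; samples at the intervention age are post
# (half-open convention)
pigment_multiplier <- function(age_ce, intervention_year, fold, width) {
  mult <- rep(1, length(age_ce))
  post <- which(age_ce >= intervention_year)
  if (length(post)) {
    post <- post[order(age_ce[post])]          # oldest post sample first
    i <- seq_along(post)
    mult[post] <- if (width > 0) 1 + (fold - 1) * pmin(i / width, 1) else fold
  }
  mult
}

#' Generate a synthetic multiproxy sediment core with known ground truth
#'
#' Produces every table the downstream pipeline consumes — 210Pb/137Cs
#' activities, reflectance spectra, pigment concentrations, bulk
#' geochemistry, and subfossil body-part counts with marker-spore tallies —
#' from a single configuration, together with the planted truth needed for
#' parameter-recovery testing.
#'
#' Construction, per sample mid-depth z with true age t(z) = z / sedimentation
#' rate: total 210Pb activity is `supported + flux * exp(-lambda * t) *
#' (1 + e)` with `e ~ N(0, activity_cv)`; pigments are lognormal around a
#' per-pigment baseline times a step-ramp multiplier reaching
#' `pigment_fold_change` after the intervention year; cladoceran body-part
#' counts are Poisson with means reduced by `cladoceran_decline_frac` after
#' the collapse year; marker spores are rounded normal draws truncated at 1;
#' spectra are a flat continuum minus a Gaussian trough centred in the
#' 655-680 nm window with depth proportional to the per-sample pigment sum.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `"core_data"` with elements `activity`, `spectra`
#'   (a `spectral_cube`), `pigments`, `geochem`, `counts`, `truth`
#'   (a `synthetic_truth`), and `config`.
#' @examples
#' core <- generate_core(synthetic_config(seed = 42))
#' head(core$activity)
#' truth_report(core$truth)
#' @export
generate_core <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  cfg <- config
  with_seed(cfg$seed, {
    th <- cfg$sample_thickness_cm
    depth_top <- seq(0, cfg$core_length_cm - th, by = th)
    depth_bottom <- depth_top + th
    depth_mid <- (depth_top + depth_bottom) / 2
    n <- length(depth_mid)
    age_true <- cfg$surface_year - depth_mid / cfg$sed_rate_cm_yr
    dry_mass_cum <- cfg$dry_bulk_density_g_cm3 * depth_mid

    # --- 210Pb / 137Cs activities -------------------------------------
    t_elapsed <- cfg$surface_year - age_true
    unsupported <- cfg$pb210_flux * exp(-PB210_LAMBDA * t_elapsed)
    eps <- if (cfg$activity_cv > 0) stats::rnorm(n, 0, cfg$activity_cv) else 0
    total <- cfg$supported_pb210 + unsupported * (1 + eps)
    err <- cfg$activity_cv * (cfg$supported_pb210 + unsupported)
    cs_eps <- if (cfg$activity_cv > 0) stats::rnorm(n, 0, cfg$activity_cv) else 0
    cs137 <- pmax(0, 2 * exp(-depth_mid / 10) * (1 + cs_eps))
    activity <- data.frame(
      depth_top_cm = depth_top, depth_bottom_cm = depth_bottom,
      depth_mid_cm = depth_mid, dry_mass_cum_g_cm2 = dry_mass_cum,
      total_pb210_bq_kg = total, total_pb210_err = err,
      cs137_bq_kg = cs137, cs137_err = 0.2 * cs137
    )

    # --- pigments ------------------------------------------------------
    base <- pigment_baselines()
    mult <- pigment_multiplier(age_true, cfg$intervention_year,
                               cfg$pigment_fold_change, cfg$transition_samples)
    cy_mult <- rep(1, n)
    if (cfg$cyano_second_rise)
      cy_mult[age_true >= cfg$cyano_rise_year] <- cfg$cyano_fold
    pig_list <- lapply(names(base), function(p) {
      m <- base[[p]] * mult * (if (p %in% cyano_pigments()) cy_mult else 1)
      noise <- if (cfg$pigment_noise_sdlog > 0) {
        z <- stats::rnorm(n, 0, cfg$pigment_noise_sdlog)
        if (cfg$ar1_rho != 0)
          z <- as.numeric(stats::filter(z * sqrt(1 - cfg$ar1_rho^2), cfg$ar1_rho,
                                        method = "recursive"))
        exp(z)
      } else 1
      data.frame(depth_cm = depth_mid, pigment = p, conc = m * noise,
                 units = "nmol_g_ds", stringsAsFactors = FALSE)
    })
    pigments <- do.call(rbind, pig_list)

    # --- reflectance spectra ------------------------------------------
    wl <- 590:730
    pig_sum <- tapply(pigments$conc, pigments$depth_cm, sum)
    pig_sum <- as.numeric(pig_sum[match(as.character(depth_mid), names(pig_sum))])
    trough_scale <- 0.35 / (sum(base) * cfg$pigment_fold_change)
    trough_depth <- trough_scale * pig_sum
    shape <- exp(-((wl - 667.5)^2) / (2 * 6^2))
    refl <- outer(trough_depth, shape, function(d, s) 0.5 - d * s)
    if (cfg$spectra_noise_sd > 0)
      refl <- refl + stats::rnorm(length(refl), 0, cfg$spectra_noise_sd)
    refl <- pmin(pmax(refl, 0.01), 1)
    spectra <- spectral_cube(depth = depth_mid, wavelength = wl,
                             reflectance = refl)

    # --- bulk geochemistry --------------------------------------------
    prod_frac <- (mult - 1) / max(cfg$pigment_fold_change - 1, 1e-12)
    # TC is held flat so OC normalization rescales pigments uniformly and
    # the planted fold change stays identified; the C:N decline is planted
    # through rising TN
    tc <- rep(5, n)
    cn_atomic <- 11 - 1.7 * prod_frac
    tn <- tc * 14.007 / (12.011 * cn_atomic)
    d13c <- -23.5 - 1.2 * prod_frac
    d15n <- 0.85 + 0.1 * prod_frac
    if (cfg$geochem_noise_sd > 0) {
      tc <- pmax(0.1, tc + stats::rnorm(n, 0, cfg$geochem_noise_sd))
      tn <- pmax(0.01, tn + stats::rnorm(n, 0, cfg$geochem_noise_sd / 10))
      d13c <- d13c + stats::rnorm(n, 0, cfg$geochem_noise_sd)
      d15n <- d15n + stats::rnorm(n, 0, cfg$geochem_noise_sd / 2)
    }
    geochem <- data.frame(depth_cm = depth_mid, tc_pct = tc, tn_pct = tn,
                          d13c_permil = d13c, d15n_permil = d15n)

    # --- subfossil counts & marker spores -----------------------------
    sub <- subfossil_baselines()
    # samples younger than (deposited after) the collapse carry the decline
    collapse_mult <- ifelse(age_true >= cfg$collapse_year,
                            1 - cfg$cladoceran_decline_frac, 1)
    spores_added <- pmax(1, round(stats::rnorm(n, cfg$spore_mean, cfg$spore_sd)))
    spores_counted <- stats::rbinom(n, spores_added, cfg$spore_count_fraction)
    cnt_list <- lapply(seq_len(nrow(sub)), function(i) {
      m <- sub$mean_count[i] * (if (sub$declines[i]) collapse_mult else 1)
      data.frame(depth_cm = depth_mid, taxon = sub$taxon[i],
                 body_part = sub$body_part[i],
                 count = stats::rpois(n, m),
                 sample_volume_cm3 = cfg$sample_volume_cm3,
                 spores_counted = spores_counted,
                 spores_added = spores_added,
                 stringsAsFactors = FALSE)
    })
    counts <- do.call(rbind, cnt_list)

    # --- planted truth -------------------------------------------------
    post_p <- age_true >= cfg$intervention_year
    post_c <- age_true >= cfg$collapse_year
    lnorm_mean <- exp(cfg$pigment_noise_sdlog^2 / 2)
    pre_post <- rbind(
      data.frame(proxy = names(base),
                 changepoint_year = cfg$intervention_year,
                 pre_mean = unname(base) * lnorm_mean,
                 post_mean = unname(base) * mean(mult[post_p]) * lnorm_mean,
                 stringsAsFactors = FALSE),
      data.frame(proxy = unique(sub$taxon[sub$declines]),
                 changepoint_year = cfg$collapse_year,
                 pre_mean = NA_real_, post_mean = NA_real_,
                 stringsAsFactors = FALSE)
    )
    clad <- sub[sub$declines, ]
    for (tx in unique(clad$taxon)) {
      tot <- sum(clad$mean_count[clad$taxon == tx])
      i <- pre_post$proxy == tx
      pre_post$pre_mean[i] <- tot
      pre_post$post_mean[i] <- tot * (1 - cfg$cladoceran_decline_frac)
    }
    truth <- structure(list(
      true_age_per_depth = data.frame(depth_cm = depth_mid, age_ce = age_true),
      true_sed_rate_cm_yr = cfg$sed_rate_cm_yr,
      true_mar_g_cm2_yr = cfg$sed_rate_cm_yr * cfg$dry_bulk_density_g_cm3,
      true_intervention_depth = (cfg$surface_year - cfg$intervention_year) *
        cfg$sed_rate_cm_yr,
      true_collapse_depth = (cfg$surface_year - cfg$collapse_year) *
        cfg$sed_rate_cm_yr,
      intervention_year = cfg$intervention_year,
      collapse_year = cfg$collapse_year,
      pigment_fold_change = cfg$pigment_fold_change,
      cladoceran_decline_frac = cfg$cladoceran_decline_frac,
      true_pre_post_means = pre_post,
      seed = cfg$seed
    ), class = "synthetic_truth")

    structure(list(activity = activity, spectra = spectra,
                   pigments = pigments, geochem = geochem, counts = counts,
                   truth = truth, config = cfg),
              class = "core_data")
  })
}

#' Flat table of the parameters planted in a synthetic core
#'
#' @param truth the `synthetic_truth` element returned by [generate_core()].
#' @return A data frame with columns `parameter` and `value`, one row per
#'   planted scalar (sedimentation rate, intervention/collapse depths and
#'   years, fold change, decline fraction, seed), used by
#'   parameter-recovery tests.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.frame(
    parameter = c("sed_rate_cm_yr", "mar_g_cm2_yr",
                  "intervention_year", "intervention_depth_cm",
                  "collapse_year", "collapse_depth_cm",
                  "pigment_fold_change", "cladoceran_decline_frac", "seed"),
    value = c(truth$true_sed_rate_cm_yr, truth$true_mar_g_cm2_yr,
              truth$intervention_year, truth$true_intervention_depth,
              truth$collapse_year, truth$true_collapse_depth,
              truth$pigment_fold_change, truth$cladoceran_decline_frac,
              truth$seed)
  )
}

#' @export
print.core_data <- function(x, ...) {
  cat("Synthetic multiproxy core\n")
  cat(sprintf("  %d samples, %.0f cm, surface %g CE, seed %d\n",
              nrow(x$activity), x$config$core_length_cm,
              x$config$surface_year, x$config$seed))
  cat(sprintf("  planted: intervention %g CE (fold %.2g), collapse %g CE (decline %.0f%%)\n",
              x$config$intervention_year, x$config$pigment_fold_change,
              x$config$collapse_year, 100 * x$config$cladoceran_decline_frac))
  invisible(x)
}
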