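#' Configuration of the full multiproxy pipeline
#'
#' Collects every stage parameter into a single validated list that
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]). When `input_dir` is `NULL` the pipeline starts
#' by simulating a synthetic core from the `simulate` sub-list; otherwise it
#' reads the standard CSVs (`activity.csv`, `spectra.csv`, `pigments.csv`,
#' `geochem.csv`, `counts.csv`) from `input_dir`.
#'
#' @param input_dir directory of input CSVs, or `NULL` to simulate.
#' @param output_dir where per-stage CSVs and the run manifest are written
#'   (`NULL` for an in-memory run).
#' @param simulate named list of [synthetic_config()] overrides.
#' @param collection_year sediment-surface year (CE).
#' @param lambda 210Pb decay constant (1/yr).
#' @param tail_n lowermost samples averaged for supported 210Pb.
#' @param age_method chronology used downstream: `"CFCS"` or `"CRS"`.
#' @param mc_draws Monte-Carlo replicates for the CRS age band.
#' @param smooth_k moving-average window (samples) for the TChl series.
#' @param bin_cm depth-bin width (cm) for the binned TChl series.
#' @param rabd_left,rabd_right,trough RABD continuum endpoints and trough
#'   window (nm).
#' @param log_pigments log-transform pigments before clustering.
#' @param log_offset pseudo-offset for the log transform.
#' @param scale_unit_variance scale clustering variables to unit variance in
#'   addition to centring.
#' @param intervention_year intervention point (CE) for the RIA split.
#' @param cladoceran_changepoint_year optional second split year (CE) at
#'   which a changepoint-referenced cladoceran RIA is additionally run.
#' @param ref_year Suess-correction reference year (CE).
#' @param n_perm RIA permutations per variable.
#' @param seed master seed for all stochastic stages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            simulate = list(),
                            collection_year = 2018,
                            lambda = PB210_LAMBDA,
                            tail_n = 5L,
                            age_method = c("CFCS", "CRS"),
                            mc_draws = 300L,
                            smooth_k = 13L,
                            bin_cm = 2,
                            rabd_left = 590, rabd_right = 730,
                            trough = c(655, 680),
                            log_pigments = TRUE,
                            log_offset = 0,
                            scale_unit_variance = FALSE,
                            intervention_year = 1920,
                            cladoceran_changepoint_year = NULL,
                            ref_year = 1900,
                            n_perm = 1000L,
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              simulate = simulate, collection_year = collection_year,
              lambda = lambda, tail_n = as.integer(tail_n),
              age_method = match.arg(age_method),
              mc_draws = as.integer(mc_draws),
              smooth_k = as.integer(smooth_k), bin_cm = bin_cm,
              rabd_left = rabd_left, rabd_right = rabd_right,
              trough = trough, log_pigments = isTRUE(log_pigments),
              log_offset = log_offset,
              scale_unit_variance = isTRUE(scale_unit_variance),
              intervention_year = intervention_year,
              cladoceran_changepoint_year = cladoceran_changepoint_year,
              ref_year = ref_year, n_perm = as.integer(n_perm),
              seed = as.integer(seed))
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    stop("`input_dir` does not exist: ", cfg$input_dir, call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for the writer).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pivot_wide <- function(long, value_col, name_col) {
  depths <- sort(unique(long$depth_cm))
  vars <- unique(long[[name_col]])
  m <- matrix(NA_real_, length(depths), length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) {
    s <- long[long[[name_col]] == v, ]
    m[match(s$depth_cm, depths), v] <- s[[value_col]]
  }
  list(depth = depths, matrix = m)
}

#' Run the full multiproxy pipeline
#'
#' Executes, in order: simulate or ingest; supported-210Pb estimation and
#' CFCS/CRS age modelling; the RABD chloropigment series (smoothed and
#' depth-binned); pigment OC-normalization and preservation index; bulk
#' geochemistry (atomic C:N, Suess-corrected d13C); subfossil MNI,
#' concentration and influx; CONISS zonation of the pigment assemblage with
#' broken-stick zone counts; and the randomized intervention analysis of
#' pigments and cladoceran concentrations split at the intervention year.
#' Per-stage CSVs and a YAML run manifest (package version, seeds, stage
#' status and timing, parameter values) are written when `output_dir` is
#' set; stage progress is logged to stderr.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `"pipeline_result"` with the per-stage objects
#'   (`core`, `supported`, `age_cfcs`, `age_crs`, `age_model`, `tchl`,
#'   `tchl_binned`, `pigments`, `cpi`, `geochem`, `abundance`, `zonation`,
#'   `intervention_depth`, `ria_pigments`, `ria_cladocera`, optionally
#'   `ria_cladocera_changepoint`, and `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package = "paleocore",
                   version = as.character(utils::packageVersion("paleocore")),
                   seed = config$seed, stages = list())
  out <- list(config = config)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[paleocore] stage %-12s ...", name), appendLF = FALSE)
    res <- tryCatch(force(expr), error = function(e) {
      message(" FAILED")
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    el <- proc.time()[["elapsed"]] - t0
    message(sprintf(" ok (%.2fs)", el))
    manifest$stages[[name]] <<- list(status = "ok", elapsed_s = round(el, 3))
    res
  }

  # --- ingest or simulate ---------------------------------------------
  if (is.null(config$input_dir)) {
    core <- t_stage("simulate", {
      sim_args <- utils::modifyList(list(seed = config$seed),
                                    config$simulate)
      generate_core(do.call(synthetic_config, sim_args))
    })
    activity <- core$activity
    spectra <- core$spectra
    pigments <- core$pigments
    geochem <- core$geochem
    counts <- core$counts
    out$core <- core
  } else {
    ing <- t_stage("ingest", {
      d <- config$input_dir
      list(activity = read_activity_csv(file.path(d, "activity.csv")),
           spectra = read_spectra_csv(file.path(d, "spectra.csv")),
           pigments = read_checked(file.path(d, "pigments.csv"), "pigment"),
           geochem = read_checked(file.path(d, "geochem.csv"), "geochem"),
           counts = read_checked(file.path(d, "counts.csv"), "counts"))
    })
    activity <- ing$activity; spectra <- ing$spectra
    pigments <- ing$pigments; geochem <- ing$geochem; counts <- ing$counts
  }

  # --- geochronology ---------------------------------------------------
  out$supported <- t_stage("supported",
    estimate_supported(activity, tail_n = config$tail_n))
  prof <- unsupported_activity(activity, out$supported,
                               exclude_tail_n = config$tail_n)
  out$age_cfcs <- t_stage("cfcs",
    fit_cfcs(prof, config$collection_year, lambda = config$lambda))
  out$age_crs <- t_stage("crs",
    fit_crs(prof, config$collection_year, lambda = config$lambda,
            mc_draws = config$mc_draws, seed = config$seed + 101L))
  out$age_model <- if (config$age_method == "CFCS") out$age_cfcs else out$age_crs

  # --- spectral index --------------------------------------------------
  out$tchl <- t_stage("tchl",
    rabd_series(spectra, left_nm = config$rabd_left,
                right_nm = config$rabd_right, trough = config$trough,
                smooth_k = min(config$smooth_k,
                               length(spectra$depth) -
                                 (1 - length(spectra$depth) %% 2))))
  out$tchl_binned <- bin_by_depth(out$tchl$depth_cm, out$tchl$rabd,
                                  config$bin_cm)

  # --- pigments & geochemistry ----------------------------------------
  pp <- t_stage("pigments", process_pigments(pigments, geochem))
  out$pigments <- pp$normalized
  out$cpi <- pp$cpi
  out$geochem <- t_stage("geochem", {
    g <- geochem
    g$cn_atomic <- atomic_cn(g$tc_pct, g$tn_pct)
    g$age_ce <- stats::approx(out$age_model$depth_cm, out$age_model$age_ce,
                              xout = g$depth_cm, rule = 2)$y
    crv <- default_suess_curve()
    yr <- pmin(pmax(g$age_ce, min(crv$year_ce)), max(crv$year_ce))
    g$d13c_suess_corrected <- suess_correct(g$d13c_permil, yr, crv,
                                            ref_year = config$ref_year)
    g
  })

  # --- subfossils ------------------------------------------------------
  out$abundance <- t_stage("subfossils",
    subfossil_abundance(counts, age_model = out$age_model))

  # --- zonation --------------------------------------------------------
  out$zonation <- t_stage("zones", {
    pw <- pivot_wide(out$pigments, "conc", "pigment")
    mat <- strat_transform(pw$matrix,
                           log_vars = if (config$log_pigments)
                             colnames(pw$matrix) else character(),
                           offset = config$log_offset,
                           scale_unit_variance = config$scale_unit_variance)
    cn <- coniss(mat, depth = pw$depth)
    z <- broken_stick_zones(cn)
    list(coniss = cn, zones = z)
  })

  # --- intervention analysis ------------------------------------------
  ria <- t_stage("ria", {
    id <- depth_for_year(out$age_model, config$intervention_year)
    pw <- pivot_wide(out$pigments, "conc", "pigment")
    pig <- batch_ria(pw$matrix, pw$depth, id$depth,
                     n_perm = config$n_perm, seed = config$seed + 200L)
    cw <- pivot_wide(out$abundance[out$abundance$taxon != "Chaoborus", ],
                     "conc_ind_cm3", "taxon")
    clad <- batch_ria(cw$matrix, cw$depth, id$depth,
                      n_perm = config$n_perm, seed = config$seed + 300L)
    clad_cp <- NULL
    if (!is.null(config$cladoceran_changepoint_year)) {
      cd <- depth_for_year(out$age_model, config$cladoceran_changepoint_year)
      clad_cp <- batch_ria(cw$matrix, cw$depth, cd$depth,
                           n_perm = config$n_perm,
                           seed = config$seed + 400L)
    }
    list(id = id, pig = pig, clad = clad, clad_cp = clad_cp)
  })
  out$intervention_depth <- ria$id
  out$ria_pigments <- ria$pig
  out$ria_cladocera <- ria$clad
  out$ria_cladocera_changepoint <- ria$clad_cp

  out$manifest <- manifest

  if (!is.null(config$output_dir)) {
    t_stage("write", {
      d <- config$output_dir
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      s <- config$seed
      write_pipeline_csv(as.data.frame(out$age_cfcs), file.path(d, "age_cfcs.csv"), s)
      write_pipeline_csv(as.data.frame(out$age_crs), file.path(d, "age_crs.csv"), s)
      write_pipeline_csv(out$tchl, file.path(d, "tchl.csv"), s)
      write_pipeline_csv(out$tchl_binned, file.path(d, "tchl_binned.csv"), s)
      write_pipeline_csv(out$pigments, file.path(d, "pigments_oc.csv"), s)
      write_pipeline_csv(out$cpi, file.path(d, "cpi.csv"), s)
      write_pipeline_csv(out$geochem, file.path(d, "geochem_derived.csv"), s)
      write_pipeline_csv(out$abundance, file.path(d, "subfossil_abundance.csv"), s)
      write_pipeline_csv(out$zonation$coniss$merges, file.path(d, "coniss_merges.csv"), s)
      write_pipeline_csv(out$zonation$zones$zone_table, file.path(d, "zones.csv"), s)
      write_pipeline_csv(out$ria_pigments, file.path(d, "ria_pigments.csv"), s)
      write_pipeline_csv(out$ria_cladocera, file.path(d, "ria_cladocera.csv"), s)
      if (!is.null(out$ria_cladocera_changepoint))
        write_pipeline_csv(out$ria_cladocera_changepoint,
                           file.path(d, "ria_cladocera_changepoint.csv"), s)
      if (!is.null(out$core))
        write_core_csvs(out$core, file.path(d, "synthetic_input"))
      manifest$stages <- out$manifest$stages
      yaml::write_yaml(manifest, file.path(d, "manifest.yml"))
      NULL
    })
    out$manifest <- manifest
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("paleocore pipeline result\n")
  cat(sprintf("  age model: %s; intervention depth %.2f cm\n",
              attr(x$age_model, "method"), x$intervention_depth$depth))
  cat(sprintf("  zones: %d; significant pigments (p<=0.05): %d/%d\n",
              x$zonation$zones$n_zones,
              sum(x$ria_pigments$p_add_one <= 0.05, na.rm = TRUE),
              nrow(x$ria_pigments)))
  invisible(x)
}
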