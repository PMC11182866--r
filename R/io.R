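# CSV interchange: every table the pipeline reads or writes is UTF-8 CSV
# with a header row and dot decimals. Readers validate against a schema
# registry; writers emit a `# seed:`/metadata comment line when asked.

csv_schemas <- function() {
  list(
    activity = list(
      required = c("depth_top_cm", "depth_bottom_cm", "depth_mid_cm",
                   "dry_mass_cum_g_cm2", "total_pb210_bq_kg", "total_pb210_err"),
      optional = c("cs137_bq_kg", "cs137_err"),
      depth_col = "depth_mid_cm"
    ),
    age_model = list(
      required = c("depth_cm", "age_ce", "age_lo", "age_hi", "sed_rate_cm_yr"),
      optional = c("mar_g_cm2_yr", "extrapolated"),
      depth_col = "depth_cm"
    ),
    spectra = list(required = "depth_cm", optional = character(),
                   depth_col = "depth_cm", wide_wavelengths = TRUE),
    pigment = list(required = c("depth_cm", "pigment", "conc", "units"),
                   optional = character(), depth_col = NULL,
                   unit_values = c("nmol_g_ds", "nmol_g_oc")),
    geochem = list(required = c("depth_cm", "tc_pct", "tn_pct",
                                "d13c_permil", "d15n_permil"),
                   optional = character(), depth_col = "depth_cm"),
    counts = list(required = c("depth_cm", "taxon", "body_part", "count",
                               "sample_volume_cm3", "spores_counted",
                               "spores_added"),
                  optional = character(), depth_col = NULL),
    suess = list(required = c("year_ce", "d13c_atm_permil"),
                 optional = character(), depth_col = NULL),
    strat_matrix = list(required = "depth_cm", optional = character(),
                        depth_col = "depth_cm", wide_wavelengths = FALSE)
  )
}

#' Validate a pipeline CSV against a registered schema
#'
#' Checks column presence, numeric types, unit tags, and depth monotonicity.
#' Failures are collected into a machine-readable report rather than raised.
#'
#' @param path CSV file path.
#' @param schema_name one of `"activity"`, `"age_model"`, `"spectra"`,
#'   `"pigment"`, `"geochem"`, `"counts"`, `"suess"`, `"strat_matrix"`.
#' @return A list `ok` (logical), `path`, `schema`, and `failures`
#'   (data frame `row`, `column`, `message`; row `NA` for file-level issues).
#' @export
validate_csv <- function(path, schema_name) {
  schemas <- csv_schemas()
  if (!schema_name %in% names(schemas))
    stop("unknown schema: ", schema_name, call. = FALSE)
  sch <- schemas[[schema_name]]
  fail <- data.frame(row = integer(), column = character(),
                     message = character(), stringsAsFactors = FALSE)
  add <- function(row, column, message)
    rbind(fail, data.frame(row = row, column = column, message = message,
                           stringsAsFactors = FALSE))
  if (!file.exists(path)) {
    fail <- add(NA_integer_, NA_character_, paste("file not found:", path))
    return(list(ok = FALSE, path = path, schema = schema_name, failures = fail))
  }
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(sch$required, names(df))
  for (mc in missing_cols)
    fail <- add(NA_integer_, mc, "required column missing")
  if (isTRUE(sch$wide_wavelengths)) {
    wl_cols <- setdiff(names(df), "depth_cm")
    wl <- suppressWarnings(as.numeric(wl_cols))
    if (anyNA(wl))
      fail <- add(NA_integer_, NA_character_,
                  "non-numeric wavelength column header(s)")
    else if (any(diff(wl) <= 0))
      fail <- add(NA_integer_, NA_character_,
                  "wavelength columns not strictly increasing")
  }
  for (col in intersect(sch$required, names(df))) {
    if (col %in% c("pigment", "taxon", "body_part", "units")) next
    if (!is.numeric(df[[col]])) {
      fail <- add(NA_integer_, col, "column is not numeric")
    } else if (anyNA(df[[col]])) {
      fail <- add(which(is.na(df[[col]]))[1], col, "missing values")
    }
  }
  if (!is.null(sch$depth_col) && sch$depth_col %in% names(df) &&
      is.numeric(df[[sch$depth_col]])) {
    d <- df[[sch$depth_col]]
    bad <- which(diff(d) <= 0)
    if (length(bad))
      fail <- add(bad[1] + 1L, sch$depth_col,
                  "depths not strictly increasing")
  }
  if (!is.null(sch$unit_values) && "units" %in% names(df)) {
    bad <- which(!df$units %in% sch$unit_values)
    if (length(bad))
      fail <- add(bad[1], "units",
                  paste("unit tag must be one of:",
                        paste(sch$unit_values, collapse = ", ")))
  }
  list(ok = nrow(fail) == 0, path = path, schema = schema_name,
       failures = fail)
}

write_pipeline_csv <- function(df, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_checked <- function(path, schema_name) {
  rep <- validate_csv(path, schema_name)
  if (!rep$ok) {
    msg <- paste(sprintf("[row %s, col %s] %s", rep$failures$row,
                         rep$failures$column, rep$failures$message),
                 collapse = "; ")
    stop(sprintf("schema '%s' violated in %s: %s", schema_name, path, msg),
         call. = FALSE)
  }
  utils::read.csv(path, check.names = FALSE, comment.char = "#")
}

#' Read an activity profile CSV
#'
#' Expected columns: `depth_top_cm`, `depth_bottom_cm`, `depth_mid_cm`,
#' `dry_mass_cum_g_cm2`, `total_pb210_bq_kg`, `total_pb210_err`, and
#' optionally `cs137_bq_kg`, `cs137_err`. Lines starting with `#` are
#' metadata comments.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_activity_csv <- function(path) read_checked(path, "activity")

#' Read a wide spectra CSV into a spectral cube
#'
#' First column `depth_cm`; remaining column headers are wavelengths in nm.
#'
#' @param path CSV path.
#' @return A [spectral_cube()].
#' @export
read_spectra_csv <- function(path) {
  df <- read_checked(path, "spectra")
  wl <- as.numeric(setdiff(names(df), "depth_cm"))
  spectral_cube(depth = df$depth_cm, wavelength = wl,
                reflectance = as.matrix(df[, setdiff(names(df), "depth_cm")]))
}

#' Write a spectral cube as a wide CSV
#' @param cube a [spectral_cube()].
#' @param path output path.
#' @param seed optional seed recorded as a metadata comment line.
#' @export
write_spectra_csv <- function(cube, path, seed = NULL) {
  df <- data.frame(depth_cm = cube$depth, check.names = FALSE)
  refl <- as.data.frame(cube$reflectance)
  names(refl) <- as.character(cube$wavelength)
  write_pipeline_csv(cbind(df, refl), path, seed)
}

#' Write all tables of a synthetic core to a directory
#'
#' Emits `activity.csv`, `spectra.csv`, `pigments.csv`, `geochem.csv`,
#' `counts.csv`, and `truth.csv` using the pipeline CSV schemas, each with
#' the generator seed recorded in a metadata comment line.
#'
#' @param core a `core_data` object from [generate_core()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_core_csvs <- function(core, dir) {
  stopifnot(inherits(core, "core_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- core$config$seed
  paths <- c(
    activity = file.path(dir, "activity.csv"),
    spectra = file.path(dir, "spectra.csv"),
    pigments = file.path(dir, "pigments.csv"),
    geochem = file.path(dir, "geochem.csv"),
    counts = file.path(dir, "counts.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_pipeline_csv(core$activity, paths["activity"], seed)
  write_spectra_csv(core$spectra, paths["spectra"], seed)
  write_pipeline_csv(core$pigments, paths["pigments"], seed)
  write_pipeline_csv(core$geochem, paths["geochem"], seed)
  write_pipeline_csv(core$counts, paths["counts"], seed)
  write_pipeline_csv(truth_report(core$truth), paths["truth"], seed)
  invisible(paths)
}
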