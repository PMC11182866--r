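#' Estimate supported 210Pb from the lowermost samples of a profile
#'
#' Supported (background) 210Pb is taken as the arithmetic mean of total
#' activity over the deepest `tail_n` samples, where unsupported activity has
#' decayed away. The 1-sigma uncertainty combines the reported measurement
#' errors in quadrature: `sigma = sqrt(sum(err^2)) / tail_n`.
#'
#' @param profile activity profile data frame with columns
#'   `depth_mid_cm`, `total_pb210_bq_kg`, `total_pb210_err` (see
#'   [read_activity_csv()] for the full schema).
#' @param tail_n number of lowermost samples to average (>= 2).
#' @param decline_threshold absolute log-slope (per cm) beyond which the tail
#'   is flagged as still declining, i.e. possibly not yet at background.
#' @return A list with `supported`, `supported_err`, `tail_n`, and
#'   `still_declining` (logical flag; a warning is also emitted).
#' @examples
#' prof <- data.frame(depth_mid_cm = 1:5, total_pb210_bq_kg = c(60, 45, 11, 12, 10),
#'                    total_pb210_err = rep(1, 5))
#' estimate_supported(prof, tail_n = 3)
#' @export
estimate_supported <- function(profile, tail_n = 5L,
                               decline_threshold = 0.05) {
  n <- nrow(profile)
  if (tail_n < 2L || tail_n > n)
    stop("`tail_n` must be between 2 and the number of samples", call. = FALSE)
  ord <- order(profile$depth_mid_cm)
  tail_idx <- utils::tail(ord, tail_n)
  act <- profile$total_pb210_bq_kg[tail_idx]
  err <- profile$total_pb210_err[tail_idx]
  supported <- mean(act)
  supported_err <- sqrt(sum(err^2)) / tail_n
  # is the tail still on the decay limb?
  slope <- stats::coef(stats::lm(log(pmax(act, 1e-12)) ~
                                   profile$depth_mid_cm[tail_idx]))[2]
  still <- is.finite(slope) && slope < -decline_threshold
  if (still)
    warning("tail activities still declining; supported 210Pb may be overestimated",
            call. = FALSE)
  list(supported = supported, supported_err = supported_err,
       tail_n = tail_n, still_declining = still)
}

#' Subtract supported activity to obtain the unsupported 210Pb profile
#'
#' Adds `supported_pb210_bq_kg`, `unsupported_pb210_bq_kg` and
#' `unsupported_err` columns. Unsupported activity is total minus supported
#' where positive; non-positive differences are set to `NA` and flagged in
#' the logical column `unsupported_missing` (they are excluded from fits but
#' retained in the table). Errors combine in quadrature.
#'
#' @param profile activity profile data frame.
#' @param supported either the list returned by [estimate_supported()] or a
#'   single activity value (Bq/kg).
#' @param supported_err 1-sigma error of `supported` when given as a number.
#' @param detection_sigma samples whose unsupported activity does not exceed
#'   `detection_sigma` times its combined error are treated as
#'   indistinguishable from background and flagged missing (excluded from
#'   fits, retained in the table). 0 keeps every positive difference.
#' @param exclude_tail_n additionally flag the lowermost `exclude_tail_n`
#'   samples (typically the ones averaged for the supported baseline), which
#'   by construction carry no usable decay signal.
#' @return The profile with the supported/unsupported columns added.
#' @export
unsupported_activity <- function(profile, supported, supported_err = 0,
                                 detection_sigma = 2, exclude_tail_n = 0L) {
  if (is.list(supported)) {
    supported_err <- supported$supported_err
    supported <- supported$supported
  }
  u <- profile$total_pb210_bq_kg - supported
  err <- sqrt(profile$total_pb210_err^2 + supported_err^2)
  miss <- u <= detection_sigma * err
  if (exclude_tail_n > 0) {
    ord <- order(profile$depth_mid_cm)
    miss[utils::tail(ord, exclude_tail_n)] <- TRUE
  }
  profile$supported_pb210_bq_kg <- supported
  profile$unsupported_pb210_bq_kg <- ifelse(u > 0, u, NA_real_)
  profile$unsupported_err <- err
  profile$unsupported_missing <- miss
  profile
}

new_age_model <- function(df, method, collection_year, lambda, mar = NA_real_,
                          diagnostics = list()) {
  structure(df,
            class = c("age_model", "data.frame"),
            method = method, collection_year = collection_year,
            lambda = lambda, mar = mar, diagnostics = diagnostics)
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("210Pb age-depth model (%s), collection year %g\n",
              attr(x, "method"), attr(x, "collection_year")))
  if (is.finite(attr(x, "mar")))
    cat(sprintf("  mass accumulation rate: %.4g g/cm^2/yr\n", attr(x, "mar")))
  cat(sprintf("  %d depths, %g to %g cm; ages %.0f to %.0f CE\n",
              nrow(x), min(x$depth_cm), max(x$depth_cm),
              max(x$age_ce, na.rm = TRUE), min(x$age_ce, na.rm = TRUE)))
  invisible(x)
}

# local dry bulk density (g/cm^3) from the cumulative dry-mass column
local_density <- function(depth, mass_cum) {
  n <- length(depth)
  if (n < 2) return(rep(NA_real_, n))
  d <- diff(mass_cum) / diff(depth)
  c(d[1], (d[-length(d)] + d[-1]) / 2, d[length(d)])[seq_len(n)]
}

#' Constant Flux Constant Sedimentation (CFCS) 210Pb age model
#'
#' Fits `ln(unsupported activity)` against cumulative dry mass by least
#' squares. Under constant 210Pb flux and constant mass accumulation the
#' slope is `-lambda / r`, so the mass accumulation rate is `r = -lambda /
#' slope` and the age at cumulative mass m is `collection_year - m / r`.
#' The 95% confidence band propagates the slope's standard error.
#'
#' @param profile profile with unsupported columns (see
#'   [unsupported_activity()]); samples flagged `unsupported_missing` are
#'   excluded from the fit but still receive model ages.
#' @param collection_year calendar year (CE) of the sediment surface.
#' @param lambda 210Pb decay constant (1/yr); default [PB210_LAMBDA].
#' @param weighted use error-weighted least squares, weights
#'   `(activity / error)^2` (the inverse variance of log activity); falls
#'   back to ordinary least squares when errors are absent or zero.
#' @return An `age_model` data frame (`depth_cm`, `age_ce`, `age_lo`,
#'   `age_hi`, `sed_rate_cm_yr`, `mar_g_cm2_yr`) with the fitted mass
#'   accumulation rate in `attr(, "mar")`.
#' @export
fit_cfcs <- function(profile, collection_year, lambda = PB210_LAMBDA,
                     weighted = TRUE) {
  ok <- !profile$unsupported_missing &
    is.finite(profile$unsupported_pb210_bq_kg)
  m <- profile$dry_mass_cum_g_cm2
  u <- profile$unsupported_pb210_bq_kg
  if (sum(ok) < 2)
    stop("CFCS needs at least 2 samples with positive unsupported activity",
         call. = FALSE)
  if (sum(ok) == 2)
    warning("CFCS fit through only two points: no residual degrees of freedom",
            call. = FALSE)
  w <- rep(1, sum(ok))
  if (weighted && all(is.finite(profile$unsupported_err[ok])) &&
      all(profile$unsupported_err[ok] > 0))
    w <- (u[ok] / profile$unsupported_err[ok])^2
  fit <- stats::lm(log(u[ok]) ~ m[ok], weights = w)
  b <- stats::coef(fit)[[2]]
  if (b >= 0)
    stop("no decay trend: log-activity slope is non-negative; CFCS undefined",
         call. = FALSE)
  se <- tryCatch(summary(fit)$coefficients[2, 2], error = function(e) NA_real_)
  if (!is.finite(se)) se <- 0
  r <- -lambda / b
  b_steep <- b - 1.96 * se    # steeper decay -> slower accumulation -> older
  b_flat <- b + 1.96 * se     # flatter decay -> faster accumulation -> younger
  age <- collection_year - m / r
  age_lo <- collection_year - m * (-b_steep) / lambda
  age_hi <- if (b_flat < 0) collection_year - m * (-b_flat) / lambda
            else rep(collection_year, length(m))
  rho <- local_density(profile$depth_mid_cm, m)
  df <- data.frame(depth_cm = profile$depth_mid_cm,
                   age_ce = age, age_lo = age_lo, age_hi = age_hi,
                   sed_rate_cm_yr = r / rho,
                   mar_g_cm2_yr = r)
  new_age_model(df, "CFCS", collection_year, lambda, mar = r,
                diagnostics = list(slope = b, slope_se = se,
                                   n_fit = sum(ok), r2 = summary(fit)$r.squared))
}

# cumulative trapezoidal integral of y over x, from x[1]
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

crs_ages_once <- function(m, u, lambda, tail_slope) {
  # extrapolate activity to the sediment-water interface with the local
  # log-slope of the two uppermost samples
  b1 <- if (length(m) >= 2 && u[1] > 0 && u[2] > 0)
    (log(u[2]) - log(u[1])) / (m[2] - m[1]) else 0
  u0 <- u[1] * exp(-b1 * m[1])
  knots_m <- c(0, m)
  knots_u <- c(u0, u)
  p <- cumtrapz(knots_m, knots_u)           # inventory surface -> depth
  tail_inv <- if (is.finite(tail_slope) && tail_slope < 0)
    u[length(u)] / (-tail_slope) else 0
  a_total <- p[length(p)] + tail_inv
  a_below <- a_total - p[-1]                # at each sample mid
  t <- ifelse(a_below > 0, log(a_total / a_below) / lambda, NA_real_)
  list(t = t, a_total = a_total, a_below = a_below, tail_inv = tail_inv)
}

#' Constant Rate of Supply (CRS) 210Pb age model with Monte-Carlo uncertainty
#'
#' The CRS model assumes a constant supply of unsupported 210Pb to the
#' sediment surface. The residual inventory below depth z,
#' `A(z)` (Bq/cm^2), is the integral of unsupported activity over cumulative
#' dry mass from z downward, and `t(z) = ln(A(0)/A(z)) / lambda`. The
#' inventory below the deepest sample is estimated by exponential-tail
#' extrapolation using the CFCS log-slope. The per-depth mass accumulation
#' rate is `lambda * A(z) / C_u(z)`. A 95% confidence band is obtained by
#' perturbing the unsupported activities with their 1-sigma errors over
#' `mc_draws` seeded Monte-Carlo replicates.
#'
#' @inheritParams fit_cfcs
#' @param mc_draws number of Monte-Carlo replicates (0 disables the band).
#' @param seed RNG seed for the Monte-Carlo band.
#' @param tail_warn_frac warn "inventory truncated" when the extrapolated
#'   tail exceeds this fraction of the total inventory.
#' @return An `age_model` data frame with per-depth sedimentation and mass
#'   accumulation rates; diagnostics carry the total inventory and the tail
#'   fraction.
#' @export
fit_crs <- function(profile, collection_year, lambda = PB210_LAMBDA,
                    mc_draws = 500L, seed = NULL, tail_warn_frac = 0.15) {
  ok <- !profile$unsupported_missing &
    is.finite(profile$unsupported_pb210_bq_kg)
  if (sum(ok) < 3)
    stop("CRS needs at least 3 samples with positive unsupported activity",
         call. = FALSE)
  m <- profile$dry_mass_cum_g_cm2[ok]
  u <- profile$unsupported_pb210_bq_kg[ok]
  err <- profile$unsupported_err[ok]
  # tail slope from the (error-weighted) CFCS regression
  w <- if (all(err > 0)) (u / err)^2 else rep(1, length(u))
  tail_slope <- stats::coef(stats::lm(log(u) ~ m, weights = w))[[2]]
  base <- crs_ages_once(m, u, lambda, tail_slope)
  if (any(base$a_below <= 0))
    stop("residual inventory A(z) <= 0; CRS ages undefined at depth",
         call. = FALSE)
  if (base$tail_inv / base$a_total > tail_warn_frac)
    warning(sprintf("inventory truncated: %.0f%% of total inventory lies below the deepest sample",
                    100 * base$tail_inv / base$a_total), call. = FALSE)
  age <- collection_year - base$t
  mar <- lambda * base$a_below / u
  rho <- local_density(profile$depth_mid_cm[ok], m)

  age_lo <- age_hi <- rep(NA_real_, length(m))
  if (mc_draws > 0) {
    draws <- with_seed(seed, {
      vapply(seq_len(mc_draws), function(i) {
        ui <- pmax(u + stats::rnorm(length(u), 0, err), 1e-9)
        bs <- tryCatch(stats::coef(stats::lm(log(ui) ~ m))[[2]],
                       error = function(e) tail_slope)
        res <- crs_ages_once(m, ui, lambda, bs)
        collection_year - res$t
      }, numeric(length(m)))
    })
    age_lo <- apply(draws, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
    age_hi <- apply(draws, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  }
  df <- data.frame(depth_cm = profile$depth_mid_cm[ok],
                   age_ce = age, age_lo = age_lo, age_hi = age_hi,
                   sed_rate_cm_yr = mar / rho,
                   mar_g_cm2_yr = mar)
  new_age_model(df, "CRS", collection_year, lambda,
                diagnostics = list(a_total = base$a_total,
                                   tail_fraction = base$tail_inv / base$a_total,
                                   mc_draws = mc_draws, seed = seed))
}

#' Transfer a chronology to an undated core through stratigraphic tie points
#'
#' Maps each depth of an undated core onto the dated core's depth scale by
#' piecewise-linear interpolation between correlation tie points (for
#' example, matched features of the hyperspectral chloropigment profiles),
#' then evaluates the dated core's age model at the mapped depths.
#' Depths beyond the outermost tie points are linearly extrapolated with the
#' outer tie segment's slope and flagged in the `extrapolated` column.
#'
#' @param undated_depths numeric depths (cm) of the undated core.
#' @param tie_points data frame with columns `undated_depth` and
#'   `dated_depth`, strictly increasing in both.
#' @param dated an `age_model` for the dated core.
#' @return An `age_model` (method `"tie-point"`) with an extra logical
#'   `extrapolated` column; mapped depths outside the dated model's span get
#'   `NA` ages.
#' @export
transfer_chronology <- function(undated_depths, tie_points, dated) {
  stopifnot(inherits(dated, "age_model"))
  if (nrow(tie_points) < 2)
    stop("need at least 2 tie points", call. = FALSE)
  tp <- tie_points[order(tie_points$undated_depth), , drop = FALSE]
  if (any(diff(tp$undated_depth) <= 0) || any(diff(tp$dated_depth) <= 0))
    stop("tie points must be strictly monotone in both depth scales",
         call. = FALSE)
  span <- range(dated$depth_cm)
  if (any(tp$dated_depth < span[1] - 1e-9 | tp$dated_depth > span[2] + 1e-9))
    stop("tie depth outside dated model span", call. = FALSE)
  inside <- undated_depths >= tp$undated_depth[1] &
    undated_depths <= tp$undated_depth[nrow(tp)]
  mapped <- stats::approx(tp$undated_depth, tp$dated_depth,
                          xout = undated_depths, rule = 1)$y
  # linear extrapolation with the outer segments, flagged
  k <- nrow(tp)
  s_lo <- (tp$dated_depth[2] - tp$dated_depth[1]) /
    (tp$undated_depth[2] - tp$undated_depth[1])
  s_hi <- (tp$dated_depth[k] - tp$dated_depth[k - 1]) /
    (tp$undated_depth[k] - tp$undated_depth[k - 1])
  lo <- undated_depths < tp$undated_depth[1]
  hi <- undated_depths > tp$undated_depth[k]
  mapped[lo] <- tp$dated_depth[1] + s_lo * (undated_depths[lo] - tp$undated_depth[1])
  mapped[hi] <- tp$dated_depth[k] + s_hi * (undated_depths[hi] - tp$undated_depth[k])
  out_of_span <- mapped < span[1] | mapped > span[2]
  interp <- function(col) {
    v <- dated[[col]]
    if (sum(is.finite(v)) < 2) return(rep(NA_real_, length(mapped)))
    y <- stats::approx(dated$depth_cm, v, xout = mapped, rule = 1)$y
    y[out_of_span] <- NA_real_
    y
  }
  df <- data.frame(depth_cm = undated_depths,
                   age_ce = interp("age_ce"),
                   age_lo = interp("age_lo"),
                   age_hi = interp("age_hi"),
                   sed_rate_cm_yr = interp("sed_rate_cm_yr"),
                   mar_g_cm2_yr = interp("mar_g_cm2_yr"),
                   extrapolated = !inside)
  new_age_model(df, "tie-point", attr(dated, "collection_year"),
                attr(dated, "lambda"),
                diagnostics = list(n_tie_points = k,
                                   source_method = attr(dated, "method")))
}
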