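# a clean exponential profile with known mass accumulation rate r
exp_profile <- function(r = 0.05, lambda = 0.03108, n = 20, flux = 200,
                        err = 0) {
  depth <- seq(0.5, by = 1, length.out = n)
  mass <- 0.1 * depth
  u <- flux * exp(-lambda * mass / r)
  data.frame(depth_top_cm = depth - 0.5, depth_bottom_cm = depth + 0.5,
             depth_mid_cm = depth, dry_mass_cum_g_cm2 = mass,
             total_pb210_bq_kg = u, total_pb210_err = err)
}

test_that("supported activity is the tail mean with quadrature errors", {
  prof <- data.frame(depth_mid_cm = 1:6,
                     total_pb210_bq_kg = c(90, 60, 40, 10, 12, 11),
                     total_pb210_err = c(3, 3, 2, 1, 1, 1))
  s <- estimate_supported(prof, tail_n = 3)
  expect_equal(s$supported, 11)
  expect_equal(s$supported_err, sqrt(3) / 3, tolerance = 1e-12)
  # all-equal tail: sigma comes only from the measurement errors
  prof$total_pb210_bq_kg <- rep(5, 6)
  s2 <- estimate_supported(prof, tail_n = 3)
  expect_equal(s2$supported, 5)
  expect_equal(s2$supported_err, sqrt(3) / 3, tolerance = 1e-12)
  expect_error(estimate_supported(prof, tail_n = 1), "between 2")
  expect_error(estimate_supported(prof, tail_n = 10), "between 2")
})

test_that("a still-declining tail is flagged", {
  prof <- data.frame(depth_mid_cm = 1:6,
                     total_pb210_bq_kg = c(200, 150, 110, 80, 60, 45),
                     total_pb210_err = rep(2, 6))
  expect_warning(s <- estimate_supported(prof, tail_n = 3), "declining")
  expect_true(s$still_declining)
})

test_that("CFCS recovers the slope -lambda/r and the rate exactly", {
  prof <- unsupported_activity(exp_profile(), 0, detection_sigma = 0)
  fit <- suppressWarnings(fit_cfcs(prof, 2018, lambda = 0.03108))
  expect_equal(attr(fit, "diagnostics")$slope, -0.6216, tolerance = 1e-9)
  expect_equal(attr(fit, "mar"), 0.05, tolerance = 1e-9)
  # age at cumulative mass m is collection_year - m / r
  expect_equal(fit$age_ce, 2018 - prof$dry_mass_cum_g_cm2 / 0.05,
               tolerance = 1e-9)
})

test_that("CFCS degenerate inputs: two points fit with warning, no trend errors", {
  prof <- unsupported_activity(exp_profile(n = 2), 0, detection_sigma = 0)
  expect_warning(fit <- fit_cfcs(prof, 2018, lambda = 0.03108),
                 "two points")
  expect_equal(attr(fit, "mar"), 0.05, tolerance = 1e-9)
  flat <- exp_profile(n = 10)
  flat$total_pb210_bq_kg <- rep(50, 10)
  prof2 <- unsupported_activity(flat, 0, detection_sigma = 0)
  expect_error(fit_cfcs(prof2, 2018), "no decay trend")
})

test_that("the detection screen flags near-background samples but keeps them", {
  prof <- exp_profile(err = 5)
  out <- unsupported_activity(prof, 140, supported_err = 0,
                              detection_sigma = 2)
  expect_true(any(out$unsupported_missing))
  # flagged but positive differences are retained in the table
  kept <- !is.na(out$unsupported_pb210_bq_kg)
  expect_true(any(out$unsupported_missing & kept))
})

test_that("CRS matches CFCS within 1% of elapsed time on a noise-free core", {
  core <- generate_core(quiet_config())
  prof <- unsupported_activity(core$activity, 30, detection_sigma = 0)
  cfcs <- suppressWarnings(fit_cfcs(prof, 2018))
  crs <- fit_crs(prof, 2018, mc_draws = 0)
  cmp <- merge(as.data.frame(cfcs)[, c("depth_cm", "age_ce")],
               as.data.frame(crs)[, c("depth_cm", "age_ce")], by = "depth_cm")
  elapsed <- pmax(2018 - cmp$age_ce.x, 1e-9)
  expect_lt(max(abs(cmp$age_ce.x - cmp$age_ce.y) / elapsed), 0.01)
  # and the recovered rate is exact
  expect_equal(attr(cfcs, "mar"), core$truth$true_mar_g_cm2_yr,
               tolerance = 1e-6)
})

test_that("CRS ages are monotone and near the collection year at the surface", {
  core <- generate_core(synthetic_config(seed = 11))
  supp <- estimate_supported(core$activity, tail_n = 5)
  prof <- unsupported_activity(core$activity, supp, exclude_tail_n = 5)
  crs <- suppressWarnings(fit_crs(prof, 2018, mc_draws = 0))
  expect_true(all(diff(crs$age_ce) < 0))
  expect_gt(crs$age_ce[1], 2018 - 6)
  expect_lte(crs$age_ce[1], 2018)
})

test_that("CRS Monte-Carlo band is seed-reproducible and widens downcore", {
  core <- generate_core(synthetic_config(seed = 4, activity_cv = 0.08))
  supp <- estimate_supported(core$activity, tail_n = 5)
  prof <- unsupported_activity(core$activity, supp, exclude_tail_n = 5)
  a <- suppressWarnings(fit_crs(prof, 2018, mc_draws = 200, seed = 9))
  b <- suppressWarnings(fit_crs(prof, 2018, mc_draws = 200, seed = 9))
  expect_identical(a$age_lo, b$age_lo)
  w <- a$age_hi - a$age_lo
  expect_gt(w[length(w)], w[1])
})

test_that("tie-point transfer maps depths then ages, flagging extrapolation", {
  dated <- structure(
    data.frame(depth_cm = 0:30, age_ce = 2018 - 5 * (0:30),
               age_lo = 2018 - 5 * (0:30) - 2, age_hi = 2018 - 5 * (0:30) + 2,
               sed_rate_cm_yr = 0.2, mar_g_cm2_yr = 0.06),
    class = c("age_model", "data.frame"),
    method = "CFCS", collection_year = 2018, lambda = PB210_LAMBDA)
  # identity tie points reproduce the dated ages
  id <- transfer_chronology(0:30, data.frame(undated_depth = c(0, 30),
                                             dated_depth = c(0, 30)), dated)
  expect_equal(id$age_ce, dated$age_ce)
  # (0,0),(10,20): undated 5 maps to dated 10; linear 2018..1918 over 20 cm
  dated2 <- structure(
    data.frame(depth_cm = seq(0, 20, 0.5),
               age_ce = seq(2018, 1918, length.out = 41),
               age_lo = NA_real_, age_hi = NA_real_,
               sed_rate_cm_yr = 0.2, mar_g_cm2_yr = 0.06),
    class = c("age_model", "data.frame"),
    method = "CFCS", collection_year = 2018, lambda = PB210_LAMBDA)
  tr <- transfer_chronology(c(5, 12), data.frame(undated_depth = c(0, 10),
                                                 dated_depth = c(0, 20)), dated2)
  expect_equal(tr$age_ce[1], 1968)
  expect_true(tr$extrapolated[2])   # beyond the outer tie point
  expect_error(
    transfer_chronology(0:10, data.frame(undated_depth = c(0, 10, 5),
                                         dated_depth = c(0, 5, 8)), dated2),
    "monotone")
})
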