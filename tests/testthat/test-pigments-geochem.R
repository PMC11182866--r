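test_that("OC normalization divides by the carbon fraction", {
  expect_equal(normalize_to_oc(10, 5), 200)
  expect_equal(normalize_to_oc(7.3, 100), 7.3)
  expect_equal(normalize_to_oc(0, 12), 0)
  expect_error(normalize_to_oc(1, 0), "0, 100")
  # homogeneity: linear in the concentration
  expect_equal(normalize_to_oc(3 * 4.2, 8), 3 * normalize_to_oc(4.2, 8))
})

test_that("CPI is the chlorophyll fraction of chlorophyll plus derivatives", {
  expect_equal(cpi(1, 4, 5), 0.1)
  expect_equal(cpi(3, 0, 0), 1.0)
  expect_equal(cpi(0, 2, 1), 0.0)
  expect_warning(v <- cpi(0, 0, 0), "undefined")
  expect_true(is.na(v))
  # bounded and monotone
  x <- cpi(seq(0, 5, 0.5), 2, 3)
  expect_true(all(x >= 0 & x <= 1))
  expect_true(all(diff(x) > 0))
  expect_true(cpi(1, 2, 3) > cpi(1, 4, 3))
  expect_error(cpi(-1, 0, 0), ">= 0")
})

test_that("pigment flux is concentration times density times rate", {
  expect_equal(pigment_flux(100, 0.5, 0.2), 10)
  expect_equal(pigment_flux(100, 0.5, 0.4), 20)   # linear in rate
  expect_equal(pigment_flux(0, 0.5, 0.2), 0)
  expect_equal(pigment_flux(2 * 7, 0.3, 0.1), 2 * pigment_flux(7, 0.3, 0.1))
  expect_error(pigment_flux(1, 0, 0.1), "> 0")
})

test_that("process_pigments normalizes and computes a per-depth CPI", {
  core <- generate_core(quiet_config())
  pp <- process_pigments(core$pigments, core$geochem)
  expect_true(all(pp$normalized$units == "nmol_g_oc"))
  # TC is 5% on the quiet core, so normalization multiplies by 20
  chl <- core$pigments[core$pigments$pigment == "chlorophyll a", ]
  nchl <- pp$normalized[pp$normalized$pigment == "chlorophyll a", ]
  expect_equal(nchl$conc, chl$conc * 20, tolerance = 1e-9)
  expect_true(all(pp$cpi$cpi > 0 & pp$cpi$cpi < 0.1))
  # renaming every pigment trips the vocabulary check, and the CPI becomes
  # undefined because the chlorophyll columns vanish
  expect_warning(
    expect_warning(process_pigments(transform(core$pigments,
                                              pigment = "mystery pigment"),
                                    core$geochem),
                   "vocabulary"),
    "undefined")
})

test_that("atomic C:N converts mass percents to a molar ratio", {
  expect_equal(atomic_cn(4.8, 0.56), 10.00, tolerance = 0.01)
  expect_equal(atomic_cn(2, 2), 14.007 / 12.011, tolerance = 1e-12)
  expect_error(atomic_cn(2, 0), "> 0")
  # equals the mass ratio times 14.007/12.011
  expect_equal(atomic_cn(3.1, 0.4), (3.1 / 0.4) * 14.007 / 12.011,
               tolerance = 1e-12)
})

test_that("Suess correction subtracts the atmospheric shift since the reference", {
  crv <- data.frame(year_ce = c(1900, 2000), d13c_atm_permil = c(-6.5, -8.0))
  expect_equal(suess_correct(-24, 1950, crv, ref_year = 1900), -23.25)
  expect_equal(suess_correct(-24, 1900, crv, ref_year = 1900), -24)
  # declining curve, year after reference: corrected exceeds measured
  expect_gt(suess_correct(-24, 1980, crv, ref_year = 1900), -24)
  expect_error(suess_correct(-24, 1800, crv, ref_year = 1900), "outside")
  # correcting with a flat curve changes nothing (idempotence guard)
  flat <- data.frame(year_ce = c(1900, 2000), d13c_atm_permil = c(-7, -7))
  expect_equal(suess_correct(-23.25, 1950, flat, ref_year = 1900), -23.25)
})

test_that("the packaged atmospheric curve declines monotonically", {
  crv <- default_suess_curve()
  expect_true(all(diff(crv$d13c_atm_permil) < 0))
  expect_true(min(crv$year_ce) <= 1900 && max(crv$year_ce) >= 2018)
})
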