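test_that("MNI is the multiplicity-adjusted most abundant body part", {
  expect_equal(mni(c(headshield = 12, carapace = 18)), 12)  # 18/2 = 9 < 12
  expect_equal(mni(c(headshield = 7)), 7)
  expect_equal(mni(c(headshield = 0, carapace = 0)), 0)
  expect_equal(mni(c(carapace = 17)), 9)                    # ceiling(17/2)
  expect_equal(mni(c(mandible = 3)), 2)
  expect_error(mni(c(antenna = 4)), "no multiplicity")
  expect_error(mni(c(headshield = -1)), "non-negative")
  expect_error(mni(integer(0)), "no body parts")
})

test_that("screened volume scales with the spore recovery fraction", {
  expect_equal(volume_screened(2, 4833, 9666), 1.0, tolerance = 0)
  expect_equal(volume_screened(2, 9666, 9666), 2)
  expect_warning(v <- volume_screened(2, 0, 9666), "zero marker spores")
  expect_equal(v, 0)
  expect_warning(volume_screened(2, 10000, 9666), "implausible")
  expect_error(volume_screened(2, 5, 0), "> 0")
})

test_that("concentration and influx follow the unit arithmetic", {
  counts <- data.frame(
    depth_cm = c(1, 1, 5, 5), taxon = "Alona",
    body_part = c("headshield", "carapace", "headshield", "carapace"),
    count = c(30, 40, 10, 28), sample_volume_cm3 = 2,
    spores_counted = 4833, spores_added = 9666)
  am <- structure(
    data.frame(depth_cm = 0:10, age_ce = 2018 - (0:10) * 10,
               age_lo = NA_real_, age_hi = NA_real_,
               sed_rate_cm_yr = 0.1, mar_g_cm2_yr = 0.03),
    class = c("age_model", "data.frame"),
    method = "CFCS", collection_year = 2018, lambda = PB210_LAMBDA)
  ab <- subfossil_abundance(counts, am)
  expect_equal(ab$mni, c(30, 14))        # max(30, 40/2), max(10, 28/2)
  expect_equal(ab$volume_screened_cm3, c(1, 1))
  expect_equal(ab$conc_ind_cm3, c(30, 14))
  # 0.1 cm/yr = 10 yr/cm, so influx = concentration / 10
  expect_equal(ab$influx_ind_cm2_yr, c(3, 1.4))
})

test_that("concentration is inversely proportional to spores counted", {
  base <- data.frame(depth_cm = 1, taxon = "Bosmina", body_part = "headshield",
                     count = 40, sample_volume_cm3 = 2,
                     spores_counted = 2000, spores_added = 9666)
  twice <- transform(base, spores_counted = 4000)
  c1 <- subfossil_abundance(base)$conc_ind_cm3
  c2 <- subfossil_abundance(twice)$conc_ind_cm3
  expect_equal(c1 / c2, 2, tolerance = 1e-12)
})

test_that("influx over concentration equals the local sedimentation rate", {
  core <- generate_core(synthetic_config(seed = 2))
  supp <- estimate_supported(core$activity, tail_n = 5)
  prof <- unsupported_activity(core$activity, supp, exclude_tail_n = 5)
  am <- fit_cfcs(prof, 2018)
  ab <- subfossil_abundance(core$counts, am)
  ok <- is.finite(ab$conc_ind_cm3) & ab$conc_ind_cm3 > 0
  sr <- approx(am$depth_cm, am$sed_rate_cm_yr, xout = ab$depth_cm[ok],
               rule = 2)$y
  expect_equal(ab$influx_ind_cm2_yr[ok] / ab$conc_ind_cm3[ok], sr,
               tolerance = 1e-9)
})

test_that("post/pre concentration ratio recovers the planted decline", {
  # parameter recovery at the planted changepoint, across seeds
  ratios <- vapply(1:25, function(s) {
    core <- generate_core(synthetic_config(seed = s))
    ab <- subfossil_abundance(core$counts)
    a <- ab[ab$taxon == "Alona", ]
    age <- core$truth$true_age_per_depth
    ages <- age$age_ce[match(a$depth_cm, age$depth_cm)]
    mean(a$conc_ind_cm3[ages >= 1957]) / mean(a$conc_ind_cm3[ages < 1957])
  }, numeric(1))
  expect_gt(mean(abs(ratios - 0.25) < 0.1), 0.9)
})
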