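test_that("the same seed reproduces the core byte for byte", {
  a <- generate_core(synthetic_config(seed = 7))
  b <- generate_core(synthetic_config(seed = 7))
  expect_identical(a$activity, b$activity)
  expect_identical(a$pigments, b$pigments)
  expect_identical(a$counts, b$counts)
  expect_identical(a$spectra$reflectance, b$spectra$reflectance)
  d <- generate_core(synthetic_config(seed = 8))
  expect_false(identical(a$activity$total_pb210_bq_kg,
                         d$activity$total_pb210_bq_kg))
})

test_that("noise-free activity equals supported + flux/2 after one half-life", {
  # 0.2-cm samples at 1 cm/yr put a sample mid exactly at t = 22.3 yr
  cfg <- quiet_config(core_length_cm = 30, sample_thickness_cm = 0.2,
                      sed_rate_cm_yr = 1, intervention_year = 2000,
                      collapse_year = 1995)
  core <- generate_core(cfg)
  i <- which(abs(core$activity$depth_mid_cm - 22.3) < 1e-9)
  expect_length(i, 1)
  expect_equal(core$activity$total_pb210_bq_kg[i],
               cfg$supported_pb210 + cfg$pb210_flux / 2, tolerance = 1e-12)
})

test_that("a step transition with zero noise plants an exact fold change", {
  cfg <- quiet_config(pigment_fold_change = 5, transition_samples = 0)
  core <- generate_core(cfg)
  age <- core$truth$true_age_per_depth$age_ce
  for (p in c("chlorophyll a", "diatoxanthin")) {
    s <- core$pigments[core$pigments$pigment == p, ]
    ratio <- mean(s$conc[age >= 1920]) / mean(s$conc[age < 1920])
    expect_equal(ratio, 5, tolerance = 1e-12)
  }
})

test_that("true chronology is strictly older with depth and truth depths match", {
  core <- generate_core(synthetic_config(seed = 3))
  ages <- core$truth$true_age_per_depth$age_ce
  expect_true(all(diff(ages) < 0))
  tr <- truth_report(core$truth)
  expect_equal(tr$value[tr$parameter == "intervention_depth_cm"],
               (2018 - 1920) * 0.21)
  # sedimentation 0.2 cm/yr, surface 2018: depth 20 cm corresponds to 1918
  cfg <- quiet_config(sed_rate_cm_yr = 0.2)
  core2 <- generate_core(cfg)
  a <- core2$truth$true_age_per_depth
  expect_equal(approx(a$depth_cm, a$age_ce, xout = 20)$y, 1918)
})

test_that("truth report carries the planted decline fraction", {
  core <- generate_core(synthetic_config(cladoceran_decline_frac = 0.75))
  tr <- truth_report(core$truth)
  expect_equal(tr$value[tr$parameter == "cladoceran_decline_frac"], 0.75)
  pp <- core$truth$true_pre_post_means
  clad <- pp[pp$proxy == "Alona", ]
  expect_equal(clad$post_mean / clad$pre_mean, 0.25)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(sed_rate_cm_yr = -1), "> 0")
  expect_error(synthetic_config(cladoceran_decline_frac = 1.2), "0, 1")
  expect_error(synthetic_config(intervention_year = 2030), "precede")
  expect_error(synthetic_config(intervention_year = 1500), "outside")
})

test_that("cladoceran counts drop after the collapse year, not before", {
  core <- generate_core(synthetic_config(seed = 5))
  age <- core$truth$true_age_per_depth$age_ce
  s <- core$counts[core$counts$taxon == "Bosmina" &
                     core$counts$body_part == "carapace", ]
  pre <- mean(s$count[match(s$depth_cm, core$truth$true_age_per_depth$depth_cm)][age < 1957])
  post <- mean(s$count[match(s$depth_cm, core$truth$true_age_per_depth$depth_cm)][age >= 1957])
  expect_lt(post, pre * 0.5)
})

test_that("RIA detects a planted fold change of 2 at default noise", {
  hits <- vapply(1:40, function(s) {
    core <- generate_core(synthetic_config(seed = s, pigment_fold_change = 2))
    sgl <- core$pigments[core$pigments$pigment == "diatoxanthin", ]
    age <- core$truth$true_age_per_depth$age_ce
    r <- ria_test(rev(sgl$conc), split_index = sum(age < 1920),
                  n_perm = 199, seed = s)
    r$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
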