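test_that("a constant series gives zero delta and p = 1", {
  r <- ria_test(rep(3, 10), split_index = 5, n_perm = 99, seed = 1)
  expect_equal(r$observed_delta, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$p_raw, 1)
})

test_that("the step series has exact exhaustive p = 0.1", {
  r <- ria_test(c(0, 0, 0, 10, 10, 10), split_index = 3, mode = "exhaustive")
  expect_equal(r$observed_delta, 10)
  expect_equal(r$p_value, 0.1, tolerance = 0)
  # and matches a full enumeration over all 720 orderings
  expect_equal(oracle_ria_p(c(0, 0, 0, 10, 10, 10), 3), 0.1)
})

test_that("sampled p converges to the exhaustive p on a length-8 series", {
  set.seed(5)
  x <- rnorm(8) + c(0, 0, 0, 0, 1.5, 1.5, 1.5, 1.5)
  ex <- ria_test(x, split_index = 4, mode = "exhaustive")
  sa <- ria_test(x, split_index = 4, n_perm = 4000, seed = 2)
  mc_err <- 3 * sqrt(ex$p_value * (1 - ex$p_value) / 4000)
  expect_lt(abs(sa$p_raw - ex$p_value), mc_err + 0.01)
})

test_that("p is invariant under affine transformation of the series", {
  set.seed(9)
  x <- rnorm(12)
  a <- ria_test(x, split_index = 6, n_perm = 499, seed = 3)
  b <- ria_test(5 * x - 2, split_index = 6, n_perm = 499, seed = 3)
  expect_equal(a$p_value, b$p_value)
  expect_equal(b$observed_delta, 5 * a$observed_delta, tolerance = 1e-12)
})

test_that("the add-one correction keeps p off zero and seeded runs repeat", {
  x <- c(rep(0, 6), rep(100, 6))
  r <- ria_test(x, split_index = 6, n_perm = 999, seed = 7)
  expect_gte(r$p_value, 1 / 1000)
  r2 <- ria_test(x, split_index = 6, n_perm = 999, seed = 7)
  expect_identical(r$p_value, r2$p_value)
  expect_error(ria_test(x, split_index = 1, n_perm = 9), "at least 2")
})

test_that("missing values are dropped with index bookkeeping", {
  x <- c(1, NA, 2, 3, 10, 11, NA, 12)
  r <- ria_test(x, split_index = 4, n_perm = 99, seed = 1)
  expect_equal(r$n_pre, 3)
  expect_equal(r$n_post, 3)
  expect_equal(r$mean_pre, 2)
  expect_equal(r$mean_post, 11)
})

test_that("depth_for_year inverts a monotone age model", {
  am <- structure(
    data.frame(depth_cm = 0:20, age_ce = seq(2018, 1918, by = -5),
               age_lo = seq(2018, 1918, by = -5) - 4,
               age_hi = seq(2018, 1918, by = -5) + 4,
               sed_rate_cm_yr = 0.2, mar_g_cm2_yr = 0.06),
    class = c("age_model", "data.frame"),
    method = "CFCS", collection_year = 2018, lambda = PB210_LAMBDA)
  d <- depth_for_year(am, 1968)
  expect_equal(d$depth, 10)
  expect_lt(d$depth_lo, 10)
  expect_gt(d$depth_hi, 10)
  expect_equal(depth_for_year(am, 2018)$depth, 0)
  expect_error(depth_for_year(am, 1800), "outside")
})

test_that("batch RIA recovers planted effects per variable", {
  core <- generate_core(synthetic_config(seed = 6))
  pig <- core$pigments[core$pigments$pigment %in%
                         c("chlorophyll a", "diatoxanthin", "lutein"), ]
  depths <- sort(unique(pig$depth_cm))
  m <- sapply(split(pig, pig$pigment), function(s)
    s$conc[match(depths, s$depth_cm)])
  tab <- batch_ria(m, depths, core$truth$true_intervention_depth,
                   n_perm = 499, seed = 11)
  expect_true(all(tab$p_add_one <= 0.05))
  expect_true(all(tab$fold_change > 3 & tab$fold_change < 7))
  expect_true(all(tab$p_bh >= tab$p_add_one - 1e-12))
  # a pure-noise variable among signal variables stays non-significant here
  set.seed(13)
  m2 <- cbind(m, noise = exp(rnorm(nrow(m), log(10), 0.2)))
  tab2 <- batch_ria(m2, depths, core$truth$true_intervention_depth,
                    n_perm = 499, seed = 11)
  expect_gt(tab2$p_add_one[tab2$variable == "noise"], 0.05)
})

test_that("serial correlation inflates the RIA type-I error (documented caveat)", {
  # not a validity claim: a demonstration that exchangeability matters
  reject <- function(rho) {
    mean(vapply(1:60, function(s) {
      set.seed(s)
      z <- rnorm(30)
      x <- as.numeric(stats::filter(z, rho, method = "recursive"))
      ria_test(x, 15, n_perm = 199, seed = s)$p_value <= 0.05
    }, logical(1)))
  }
  expect_gt(reject(0.8), reject(0))
})
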