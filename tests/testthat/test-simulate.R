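# The synthetic-cohort generator: degenerate inputs, determinism,
# calibration, censoring, latent sibling correlation, covariate trends.

test_that("degenerate inputs give an empty cohort, same seed gives identical output", {
  cfg <- generator_config(n_families = 0)
  expect_equal(nrow(simulate_cohort(cfg)), 0L)
  cfg <- generator_config(n_families = 4000, seed = 11)
  a <- simulate_cohort(cfg, debug_latent = TRUE)
  b <- simulate_cohort(cfg, debug_latent = TRUE)
  expect_identical(a, b)
})

test_that("no shared component means uncorrelated sibling outcomes", {
  cfg <- generator_config(n_families = 60000, a0 = 0, e0 = 1, h2 = 0,
                          incidence_calibration = 0.05, seed = 3,
                          sibship_dist = c(`1` = 0, `2` = 1, `3` = 0,
                                           `4` = 0, `5` = 0))
  coh <- simulate_cohort(cfg)
  wide <- coh[order(family_id, birth_order)]
  y <- matrix(wide$t1d, ncol = 2, byrow = TRUE)
  r <- cor(y[, 1], y[, 2])
  expect_lt(abs(r), 3 / sqrt(nrow(y)))  # ~3 MC SEs around zero
})

test_that("latent sibling liability correlation approaches 0.5 a0^2", {
  cfg <- generator_config(n_families = 50000, h2 = 0.8,
                          incidence_calibration = 0.01, seed = 5,
                          sibship_dist = c(`1` = 0, `2` = 1, `3` = 0,
                                           `4` = 0, `5` = 0))
  coh <- simulate_cohort(cfg, debug_latent = TRUE)
  wide <- coh[order(family_id, birth_order)]
  liab <- matrix(wide$liability_a + wide$liability_e, ncol = 2, byrow = TRUE)
  expect_equal(cor(liab[, 1], liab[, 2]), 0.5 * 0.8, tolerance = 0.02)
})

test_that("per-year cumulative incidence matches the calibration target", {
  cfg <- generator_config(n_families = 150000, seed = 19)
  coh <- simulate_cohort(cfg)
  # full-follow-up years only; binomial SE inflated slightly by the
  # within-family correlation, so use 3x an inflated SE
  for (y in c(1982, 1990, 2000)) {
    sub <- coh[coh$birth_year == y]
    target <- cfg$incidence_calibration[as.character(y)]
    se <- sqrt(target * (1 - target) / nrow(sub)) * 1.3
    expect_lt(abs(mean(sub$t1d) - target), 3 * se,
              label = sprintf("year %d", y))
  }
})

test_that("administrative censoring is respected and status matches onset", {
  cfg <- generator_config(n_families = 40000, seed = 23)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$followup_end_age ==
                    pmin(19, cfg$admin_end_year - coh$birth_year + 1)))
  cases <- coh[coh$t1d == 1L]
  expect_true(all(!is.na(cases$onset_age)))
  expect_true(all(cases$onset_age < cases$followup_end_age))
  expect_true(all(is.na(coh$onset_age[coh$t1d == 0L])))
  # late cohorts are right-truncated: no onset at ages beyond follow-up
  late <- cases[cases$birth_year == 2010]
  expect_true(all(late$onset_age < 11))
})

test_that("covariate trends reach their configured endpoints", {
  cfg <- generator_config(n_families = 80000, seed = 31)
  set.seed(99)
  cov82 <- assign_covariates(cfg, rep(1982L, 40000))
  cov10 <- assign_covariates(cfg, rep(2010L, 40000))
  expect_lt(abs(mean(cov82$maternal_smoking) - 0.30), 0.01)
  expect_lt(abs(mean(cov10$maternal_smoking) - 0.07), 0.01)
  expect_lt(abs(mean(cov82$maternal_age) - 27), 0.1)
  expect_lt(abs(mean(cov10$maternal_age) - 31), 0.1)
  # ordinal education shifts upward
  expect_gt(mean(cov10$maternal_education), mean(cov82$maternal_education))
  # flat trend: prevalence independent of birth year
  flat <- generator_config(n_families = 10,
    covariate_trends = list(x = list(type = "binary", start = 0.2, end = 0.2)))
  set.seed(1)
  c1 <- assign_covariates(flat, rep(1985L, 30000))
  c2 <- assign_covariates(flat, rep(2005L, 30000))
  pv <- suppressWarnings(chisq.test(matrix(c(sum(c1$x), 30000 - sum(c1$x),
                                             sum(c2$x), 30000 - sum(c2$x)),
                                           2))$p.value)
  expect_gt(pv, 0.001)
})

test_that("cohorts survive a CSV round trip", {
  cfg <- generator_config(n_families = 500, seed = 2)
  coh <- simulate_cohort(cfg)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$onset_age, coh$onset_age)
  expect_equal(back$t1d, coh$t1d)
})
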