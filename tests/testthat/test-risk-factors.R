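# Full-cohort vs sibling-stratified environmental associations.

test_that("eligibility follows the factor catalogue", {
  e1 <- eligibility_check("maternal_age")
  expect_false(e1$sibling_appropriate)
  expect_match(e1$reason, "monotone")
  expect_true(eligibility_check("maternal_smoking")$sibling_appropriate)
  expect_error(eligibility_check("astrology"), "unknown factor")
  expect_error(cox_sibling_stratified(tiny_cohort(), "maternal_age"),
               "not meaningful")
})

test_that("a null factor is estimated near 1 and a true hazard effect is recovered", {
  trends <- default_covariate_trends()
  trends$maternal_smoking <- list(type = "binary", start = 0.25, end = 0.25)
  cfg <- generator_config(
    n_families = 120000, incidence_calibration = 0.03, seed = 33,
    covariate_trends = trends,
    covariate_effects = list(hazard = c(maternal_smoking = -0.29)))
  coh <- simulate_cohort(cfg)
  rec <- as_survival_records(coh)
  smoking <- cox_full_cohort(rec, "maternal_smoking")
  expect_lt(abs(log(smoking$hr) + 0.29), 3.5 * smoking$log_hr_se)
  expect_lt(abs(log(smoking$hr) + 0.29), 0.1)
  # cesarean has no generated effect
  ces <- cox_full_cohort(rec, "cesarean",
                         adjustment = c("birth_year", "sex"))
  expect_lt(abs(log(ces$hr)), 3 * ces$log_hr_se)
})

test_that("adjusting for birth year removes the secular-trend confounding", {
  # cesarean prevalence rises while incidence rises: unadjusted for year the
  # HR is biased upward; adjusting restores the null
  cfg <- generator_config(n_families = 150000, seed = 35)
  rec <- as_survival_records(simulate_cohort(cfg))
  unadj <- cox_full_cohort(rec, "cesarean", adjustment = "sex")
  adj <- cox_full_cohort(rec, "cesarean", adjustment = c("birth_year", "sex"))
  expect_gt(log(unadj$hr), log(adj$hr))
  expect_lt(abs(log(adj$hr)), 3 * adj$log_hr_se)
})

test_that("family-confounded exposure shows in the cohort but not among siblings", {
  cfg <- generator_config(
    n_families = 90000, incidence_calibration = 0.02, seed = 37,
    sibship_dist = c(`1` = 0, `2` = 1, `3` = 0, `4` = 0, `5` = 0),
    shared_confounding = list(sd = 1, covariate = "maternal_bmi",
                              liability_load = 0.25))
  rec <- as_survival_records(simulate_cohort(cfg))
  full <- cox_full_cohort(rec, "maternal_bmi",
                          adjustment = c("birth_year", "sex"))
  sib <- cox_sibling_stratified(rec, "maternal_bmi",
                                adjustment = c("sex"))
  # confounded full-cohort association is clearly positive
  expect_gt(log(full$hr), 3 * full$log_hr_se)
  # the sibling design cancels the family-level confounder
  expect_lt(abs(log(sib$hr)), 3 * sib$log_hr_se)
  expect_lt(abs(log(sib$hr)), 0.5 * abs(log(full$hr)))
  expect_gt(sib$n_informative_strata, 0)
})

test_that("a true within-family effect survives the sibling design", {
  cfg <- generator_config(
    n_families = 120000, incidence_calibration = 0.02, seed = 39,
    sibship_dist = c(`1` = 0, `2` = 1, `3` = 0, `4` = 0, `5` = 0),
    covariate_effects = list(hazard = c(maternal_smoking = -0.5)))
  rec <- as_survival_records(simulate_cohort(cfg))
  full <- cox_full_cohort(rec, "maternal_smoking",
                          adjustment = c("birth_year", "sex"))
  sib <- cox_sibling_stratified(rec, "maternal_smoking",
                                adjustment = c("sex"))
  expect_equal(log(sib$hr), -0.5, tolerance = 3 * sib$log_hr_se)
  expect_equal(log(sib$hr), log(full$hr), tolerance = 0.25)
})

test_that("exposure-concordant sibships carry no information in the stratified model", {
  cfg <- generator_config(
    n_families = 30000, incidence_calibration = 0.03, seed = 41,
    sibship_dist = c(`1` = 0, `2` = 1, `3` = 0, `4` = 0, `5` = 0),
    covariate_effects = list(hazard = c(maternal_smoking = -0.4)))
  coh <- simulate_cohort(cfg)
  rec <- as_survival_records(coh)
  conc <- rec[, .(same = data.table::uniqueN(maternal_smoking) == 1L),
              by = family_id]
  sib_all <- cox_sibling_stratified(rec, "maternal_smoking",
                                    adjustment = character(0))
  pruned <- rec[rec$family_id %in% conc$family_id[!conc$same]]
  sib_pruned <- cox_sibling_stratified(pruned, "maternal_smoking",
                                       adjustment = character(0))
  expect_equal(log(sib_all$hr), log(sib_pruned$hr), tolerance = 1e-6)
})
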