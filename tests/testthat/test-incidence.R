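# Kaplan-Meier cumulative incidence and the Cox birth-cohort trend.

test_that("KM cumulative incidence matches hand calculation and closed forms", {
  # no events -> 0 at every age
  quiet <- data.table::data.table(child_id = 1:5, family_id = 1:5, sex = 0L,
                                  birth_year = 1990L, exit_age = rep(19, 5),
                                  event = 0L)
  expect_equal(cumulative_incidence(quiet, 1990, 19)$estimate, 0)
  # hand Kaplan-Meier on 4 children: events at 5 and 10, censored at 8, 19
  # S(19) = (3/4) * (1/2) -> incidence 0.625
  toy <- data.table::data.table(child_id = 1:4, family_id = 1:4, sex = 0L,
                                birth_year = 2000L,
                                exit_age = c(5, 8, 10, 19),
                                event = c(1L, 0L, 1L, 0L))
  est <- cumulative_incidence(toy, 2000, 19)
  expect_equal(est$estimate, 0.625, tolerance = 1e-12)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
  # without censoring before the horizon, KM equals the empirical fraction
  coh <- small_cohort(n_families = 5000, prevalence = 0.03, seed = 6,
                      years = 1995)
  rec <- as_survival_records(coh)
  expect_equal(cumulative_incidence(rec, 1995, 19)$estimate, mean(coh$t1d),
               tolerance = 1e-12)
  # truncated follow-up is flagged
  short <- data.table::copy(toy)[, exit_age := pmin(exit_age, 10)]
  expect_warning(res <- cumulative_incidence(short, 2000, 19), "horizon")
  expect_true(res$truncated)
})

test_that("a flat generator gives hazard ratios near 1 across years", {
  coh <- small_cohort(n_families = 60000, prevalence = 0.01, seed = 13,
                      years = c(1985, 1995, 2005))
  tr <- cox_birth_year_trend(as_survival_records(coh), reference_year = 1985)
  nonref <- tr[tr$birth_year != 1985, ]
  expect_true(all(abs(log(nonref$hr)) < 3 * nonref$log_hr_se))
  expect_equal(tr$hr[tr$birth_year == 1985], 1)
})

test_that("estimates are invariant to row order and id relabeling", {
  coh <- small_cohort(n_families = 8000, prevalence = 0.02, seed = 17,
                      years = c(1990, 2000))
  rec <- as_survival_records(coh)
  tr1 <- cox_birth_year_trend(rec, 1990)
  shuf <- rec[sample.int(nrow(rec))]
  shuf$child_id <- rev(shuf$child_id)
  tr2 <- cox_birth_year_trend(shuf, 1990)
  expect_equal(tr1$hr, tr2$hr, tolerance = 1e-8)
})

test_that("duplicating families within clusters leaves robust variance honest", {
  coh <- small_cohort(n_families = 8000, prevalence = 0.02, seed = 18,
                      years = c(1990, 2000))
  rec <- as_survival_records(coh)
  dup <- rbind(rec, rec)  # same family_id: same clusters, doubled rows
  tr <- cox_birth_year_trend(rec, 1990)
  trd <- cox_birth_year_trend(dup, 1990)
  i <- tr$birth_year == 2000
  # point estimate unchanged (up to optimiser tolerance)
  expect_equal(trd$hr[i], tr$hr[i], tolerance = 1e-4)
  # robust (cluster) SE stays ~the same; the naive SE would drop by sqrt(2)
  expect_gt(trd$log_hr_se[i] / tr$log_hr_se[i], 0.85)
  fit <- attr(tr, "fit"); fitd <- attr(trd, "fit")
  naive_ratio <- sqrt(diag(fitd$naive.var))[1] / sqrt(diag(fit$naive.var))[1]
  expect_equal(naive_ratio, 1 / sqrt(2), tolerance = 0.02)
})

test_that("cluster-robust SEs exceed naive SEs under within-family correlation", {
  # averaged over replicates: sibling outcomes are strongly correlated
  # (h2 = 0.95, common prevalence), so the sandwich variance must exceed the
  # model-based one on average
  # birth year must be family-constant for the contrast to be a
  # between-cluster covariate (clustering deflates SEs of within-cluster
  # contrasts instead)
  ratios <- vapply(1:6, function(s) {
    sib2 <- c(`1` = 0, `2` = 1, `3` = 0, `4` = 0, `5` = 0)
    c1 <- small_cohort(n_families = 4000, h2 = 0.95, prevalence = 0.08,
                       seed = 25 + s, years = 1990, sibship_dist = sib2)
    c2 <- small_cohort(n_families = 4000, h2 = 0.95, prevalence = 0.08,
                       seed = 125 + s, years = 2000, sibship_dist = sib2)
    c2$family_id <- c2$family_id + 1000000L
    coh <- rbind(c1, c2)
    fit <- attr(cox_birth_year_trend(as_survival_records(coh), 1990), "fit")
    sqrt(diag(fit$var))[1] / sqrt(diag(fit$naive.var))[1]
  }, 0)
  expect_gt(mean(ratios), 1.02)
})

test_that("age windows censor at the boundary and enter late", {
  rec <- data.table::data.table(
    child_id = 1:6, family_id = 1:6, sex = c(0L, 1L, 0L, 1L, 0L, 1L),
    birth_year = rep(c(1990L, 2000L), 3),
    exit_age = c(5, 8, 10, 15, 19, 19),
    event = c(1L, 1L, 1L, 1L, 0L, 0L))
  tr <- cox_birth_year_trend(rec, 1990, age_window = c(7, 12))
  # the age-5 case never enters; events at 8 and 10 count; 15 is censored
  used <- attr(tr, "fit")$n
  expect_equal(used, 5)
  expect_equal(sum(tr$events), 2)
})

test_that("zero-event years are flagged rather than estimated", {
  rec <- data.table::data.table(
    child_id = 1:300, family_id = 1:300, sex = rep(0:1, 150),
    birth_year = rep(c(1990L, 1995L, 2000L), each = 100),
    exit_age = rep(19, 300), event = 0L)
  idx <- which(rec$birth_year != 1995)[c(1, 5, 50, 120)]
  rec$event[idx] <- 1L
  rec$exit_age[idx] <- c(4, 9, 12, 6)
  tr <- cox_birth_year_trend(rec, 1990)
  expect_true(tr$zero_events[tr$birth_year == 1995])
  expect_true(is.na(tr$hr[tr$birth_year == 1995]))
  expect_false(anyNA(tr$hr[tr$birth_year == 2000]))
})
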