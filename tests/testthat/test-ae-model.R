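# Pair probabilities, the cell likelihood, and the AE fit.

test_that("pair probabilities reduce to the kernel and normalise", {
  p0 <- moderated_ae_params(a0 = sqrt(0.83), e0 = sqrt(0.17), tau0 = 2.45)
  same_year <- data.table::data.table(y1 = 1L, y2 = 1L, sex1 = 0L, sex2 = 0L,
                                      by1 = 1996L, by2 = 1996L, count = 1L)
  expect_equal(pair_probability(p0, same_year),
               bvn_orthant(2.45, 2.45, 0.5 * 0.83), tolerance = 1e-12)
  # independent siblings when a0 = 0
  pin <- moderated_ae_params(a0 = 0, e0 = 1, tau0 = 2.45)
  expect_equal(pair_probability(pin, same_year),
               pnorm(2.45, lower.tail = FALSE)^2, tolerance = 1e-12)
  # the four outcome patterns of any covariate key sum to 1
  set.seed(4)
  for (i in 1:20) {
    h2 <- runif(1, 0.2, 0.95)
    pr <- moderated_ae_params(a0 = sqrt(h2), e0 = sqrt(1 - h2),
                              beta_a = runif(1, -0.003, 0.003),
                              beta_e = runif(1, -0.003, 0.003),
                              tau0 = runif(1, 1, 3),
                              gamma_sex = runif(1, -0.2, 0.2),
                              gamma_year = runif(1, -0.01, 0.01))
    cells <- data.table::data.table(
      y1 = c(0L, 0L, 1L, 1L), y2 = c(0L, 1L, 0L, 1L),
      sex1 = 1L, sex2 = 0L, by1 = 1988L, by2 = 1991L, count = 1L)
    expect_equal(sum(pair_probability(pr, cells)), 1, tolerance = 1e-12)
  }
})

test_that("cell likelihood equals the uncollapsed pair-by-pair sum and is linear in counts", {
  pr <- moderated_ae_params(a0 = sqrt(0.7), e0 = sqrt(0.3), tau0 = 2.2,
                            gamma_sex = 0.1, gamma_year = 0.004)
  set.seed(9)
  pairs <- data.table::data.table(
    y1 = rbinom(10, 1, 0.3), y2 = rbinom(10, 1, 0.3),
    sex1 = rbinom(10, 1, 0.5), sex2 = rbinom(10, 1, 0.5),
    by1 = sample(1985:1995, 10, TRUE), by2 = sample(1985:1995, 10, TRUE),
    count = 1L)
  ll_uncollapsed <- sum(log(pair_probability(pr, pairs)))
  collapsed <- pairs[, .(count = sum(count)),
                     by = c("y1", "y2", "sex1", "sex2", "by1", "by2")]
  expect_equal(pair_loglik(pr, collapsed), ll_uncollapsed, tolerance = 1e-10)
  # splitting one cell into two with the same key changes nothing
  split <- rbind(collapsed, collapsed[1])
  split$count[1] <- split$count[1] - 0.5
  split$count[nrow(split)] <- 0.5
  expect_equal(pair_loglik(pr, split), pair_loglik(pr, collapsed),
               tolerance = 1e-10)
  # single unaffected cell under independence: count * log((1-p)^2)
  pin <- moderated_ae_params(a0 = 0, e0 = 1, tau0 = 2.2)
  one <- data.table::data.table(y1 = 0L, y2 = 0L, sex1 = 0L, sex2 = 0L,
                                by1 = 1996L, by2 = 1996L, count = 7L)
  pmarg <- pnorm(2.2, lower.tail = FALSE)
  expect_equal(pair_loglik(pin, one), 7 * log((1 - pmarg)^2),
               tolerance = 1e-12)
})

test_that("cell likelihood agrees with an independent quadrature oracle on a toy set", {
  pr <- moderated_ae_params(a0 = sqrt(0.83), e0 = sqrt(0.17),
                            beta_a = 0.001, beta_e = -0.001, tau0 = 2.46,
                            gamma_sex = 0.05, gamma_year = 0.003)
  set.seed(12)
  pairs <- data.table::data.table(
    y1 = rbinom(30, 1, 0.4), y2 = rbinom(30, 1, 0.4),
    sex1 = rbinom(30, 1, 0.5), sex2 = rbinom(30, 1, 0.5),
    by1 = sample(1983:2009, 30, TRUE), by2 = sample(1983:2009, 30, TRUE),
    count = 1L)
  cell_prob_quad <- function(row) {
    dy1 <- row$by1 - 1996; dy2 <- row$by2 - 1996
    a1 <- pr$a0 + pr$beta_a * dy1; e1 <- pr$e0 + pr$beta_e * dy1
    a2 <- pr$a0 + pr$beta_a * dy2; e2 <- pr$e0 + pr$beta_e * dy2
    v1 <- a1^2 + e1^2; v2 <- a2^2 + e2^2
    t1 <- (pr$tau0 - pr$gamma_sex * row$sex1 - pr$gamma_year * dy1) / sqrt(v1)
    t2 <- (pr$tau0 - pr$gamma_sex * row$sex2 - pr$gamma_year * dy2) / sqrt(v2)
    rho <- 0.5 * a1 * a2 / sqrt(v1 * v2)
    p11 <- bvn_orthant_quad(t1, t2, rho)
    p1 <- pnorm(t1, lower.tail = FALSE); p2 <- pnorm(t2, lower.tail = FALSE)
    if (row$y1 == 1 && row$y2 == 1) p11
    else if (row$y1 == 1) p1 - p11
    else if (row$y2 == 1) p2 - p11
    else 1 - p1 - p2 + p11
  }
  ll_oracle <- sum(log(vapply(seq_len(nrow(pairs)),
                              function(i) cell_prob_quad(pairs[i]), 0)))
  collapsed <- pairs[, .(count = sum(count)),
                     by = c("y1", "y2", "sex1", "sex2", "by1", "by2")]
  expect_equal(pair_loglik(pr, collapsed), ll_oracle, tolerance = 1e-7)
})

test_that("fitting requires affected pairs and respects model nesting", {
  none <- data.table::data.table(y1 = 0L, y2 = 0L, sex1 = 0L, sex2 = 0L,
                                 by1 = 1990L, by2 = 1990L, count = 100L)
  expect_error(fit_ae(none), "identifiable")

  coh <- small_cohort(n_families = 25000, h2 = 0.7, prevalence = 0.02,
                      seed = 14)
  cells <- make_sibling_pairs(coh)
  f4 <- fit_ae(cells, model = "model4")
  f2 <- fit_ae(cells, model = "model2")
  f1 <- fit_ae(cells, model = "model1")
  tol <- 1e-4
  expect_gte(f2$loglik, f4$loglik - tol)
  expect_gte(f1$loglik, f2$loglik - tol)
  expect_equal(f1$aic, 2 * f1$n_free_params - 2 * f1$loglik)
  expect_true(f4$converged)
  # truth recovery at modest scale
  expect_equal(f4$params$a0^2, 0.7, tolerance = 0.08)

  cmp <- compare_models(list(f4, f2, f1))
  lrt <- attr(cmp, "lrt")
  expect_equal(lrt$df[lrt$null == "model4" & lrt$alternative == "model1"], 2L)
  expect_equal(cmp$aic, cmp$minus2LL + 2 * cmp$n_free_params)
  # mismatched data are refused
  other <- make_sibling_pairs(small_cohort(n_families = 5000, seed = 15))
  f_other <- fit_ae(other, model = "model4")
  expect_error(compare_models(list(f4, f_other)), "different data")
})

test_that("heritability curves follow the path arithmetic", {
  flat <- moderated_ae_params(a0 = 0.9, e0 = sqrt(1 - 0.81), tau0 = 2.4)
  cv <- h2_curve(flat, 1982:2010)
  expect_true(all(abs(cv$h2 - 0.81) < 1e-12))
  expect_true(all(abs(cv$h2 + cv$e2 - 1) < 1e-15))
  up <- moderated_ae_params(a0 = 0.9, e0 = sqrt(1 - 0.81), beta_a = 0.002,
                            tau0 = 2.4)
  cvu <- h2_curve(up, 1982:2010)
  expect_true(all(diff(cvu$h2) > 0))
})

test_that("family bootstrap is seed-deterministic and orders its intervals", {
  coh <- small_cohort(n_families = 4000, h2 = 0.7, prevalence = 0.03,
                      seed = 21)
  years <- c(1985, 1996, 2005)
  b1 <- bootstrap_ci(coh, model = "model4", years = years, B = 5, seed = 77)
  b2 <- bootstrap_ci(coh, model = "model4", years = years, B = 5, seed = 77)
  expect_equal(b1, b2)
  expect_true(all(b1$ci_low <= b1$ci_high))
  expect_true(all(b1$ci_low <= b1$h2 + 1e-8 | b1$ci_high >= b1$h2 - 1e-8))
  expect_error(bootstrap_ci(coh, B = 1), "at least 2")
})
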