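# Shared in-code fixtures; everything is generated, nothing is stored.

# A tiny hand-built cohort with known family structure:
# family 1: three children, family 2: two, family 3: one.
tiny_cohort <- function() {
  data.table::data.table(
    child_id = 1:6,
    family_id = c(1L, 1L, 1L, 2L, 2L, 3L),
    sex = c(1L, 0L, 1L, 0L, 0L, 1L),
    birth_year = c(1990L, 1992L, 1995L, 2000L, 2001L, 1985L),
    birth_order = c(1L, 2L, 3L, 1L, 2L, 1L),
    t1d = c(1L, 0L, 1L, 0L, 1L, 0L),
    onset_age = c(5, NA, 14, NA, 8, NA),
    followup_end_age = c(19, 19, 19, 19, 19, 19)
  )
}

# Small flat-incidence cohort for model tests.
small_cohort <- function(n_families = 20000, h2 = 0.7, prevalence = 0.02,
                         seed = 42, years = NULL, ...) {
  cfg <- generator_config(
    n_families = n_families, h2 = h2,
    incidence_calibration = prevalence,
    birth_years = years, seed = seed, ...)
  simulate_cohort(cfg)
}

# Independent slow oracle: P(Z1 > t1, Z2 > t2) by nested 1-D quadrature of
# the bivariate normal density (no reuse of the package's kernel).
bvn_orthant_quad <- function(t1, t2, rho) {
  if (abs(rho) == 1) {
    if (rho == 1) return(stats::pnorm(max(t1, t2), lower.tail = FALSE))
    return(max(0, stats::pnorm(-t2) - stats::pnorm(t1)))
  }
  dens <- function(x, y) {
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  }
  outer_f <- function(xv) {
    vapply(xv, function(x) {
      stats::integrate(function(y) dens(x, y), lower = t2, upper = t2 + 12,
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
    }, 0)
  }
  stats::integrate(outer_f, lower = t1, upper = t1 + 12,
                   rel.tol = 1e-11, abs.tol = 1e-13)$value
}
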