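## Generator configuration: the study conditions of the synthetic registry.
##
## The defaults encode the conditions the analyses are calibrated against:
## ~2.9 million children born 1982-2010 in families of full siblings, a rare
## threshold-determined outcome whose 19-year cumulative incidence rises from
## 0.50% (1982) to 0.93% (2000) and then plateaus, heritability 0.83 on the
## liability scale, onset ages 0-18 with an observed case median of 9.9 years,
## and administrative censoring at the end of 2020.

#' Onset-age distribution specification
#'
#' A two-component mixture of Beta distributions scaled to `[0, max_age)`,
#' optionally truncated to a window `[lo, hi)`.  Disease *status* is decided
#' by the liability threshold; the age at onset is then drawn independently
#' from this distribution, so the liability model stays exact while onset
#' timing (and hence administrative right-truncation) is realistic.
#'
#' @param w Mixture weight of the early-onset component.  If `NULL` and
#'   `median_target` is given, `w` is solved so the raw distribution median
#'   equals `median_target`.
#' @param shape1_early,shape2_early,shape1_late,shape2_late Beta shape
#'   parameters of the early- and late-onset components.
#' @param max_age Upper support bound in years (exclusive).
#' @param lo,hi Truncation window in years; defaults to the full support.
#' @param median_target Optional target for the raw (untruncated) median.
#' @return An object of class `onset_dist`.
#' @export
onset_age_dist <- function(w = NULL,
                           shape1_early = 2.2, shape2_early = 4.5,
                           shape1_late = 5, shape2_late = 3,
                           max_age = 19, lo = 0, hi = max_age,
                           median_target = NULL) {
  stopifnot(max_age > 0, lo >= 0, hi > lo, hi <= max_age,
            shape1_early > 0, shape2_early > 0,
            shape1_late > 0, shape2_late > 0)
  d <- structure(list(w = w, a1 = shape1_early, b1 = shape2_early,
                      a2 = shape1_late, b2 = shape2_late,
                      max_age = max_age, lo = lo, hi = hi),
                 class = "onset_dist")
  if (is.null(w)) {
    if (is.null(median_target)) {
      stop("onset_age_dist: supply `w` or `median_target`", call. = FALSE)
    }
    d$w <- .solve_onset_weight(d, median_target)
  }
  if (d$w < 0 || d$w > 1) {
    stop("onset_age_dist: mixture weight must be in [0, 1]", call. = FALSE)
  }
  d
}

# Untruncated mixture CDF at age q (years).
.ponset_raw <- function(q, d) {
  u <- pmin(pmax(q / d$max_age, 0), 1)
  d$w * stats::pbeta(u, d$a1, d$b1) + (1 - d$w) * stats::pbeta(u, d$a2, d$b2)
}

#' @rdname onset_age_dist
#' @param q Ages (years) at which to evaluate the (truncated) CDF.
#' @param dist An `onset_dist` object.
#' @export
ponset <- function(q, dist) {
  Flo <- .ponset_raw(dist$lo, dist)
  Fhi <- .ponset_raw(dist$hi, dist)
  (pmin(pmax(.ponset_raw(q, dist), Flo), Fhi) - Flo) / (Fhi - Flo)
}

# Median of the (truncated) distribution, by root-finding on the CDF.
.onset_median <- function(dist, p = 0.5) {
  stats::uniroot(function(m) ponset(m, dist) - p,
                 interval = c(dist$lo + 1e-9, dist$hi - 1e-9),
                 tol = 1e-10)$root
}

.solve_onset_weight <- function(d, target) {
  f <- function(w) {
    d$w <- w
    .onset_median(d) - target
  }
  stats::uniroot(f, interval = c(1e-6, 1 - 1e-6), tol = 1e-10)$root
}

#' Draw onset ages
#'
#' Samples ages at onset from an [onset_age_dist()] specification, using the
#' current RNG stream.  Truncated windows are sampled by rejection.
#'
#' @param n Number of draws (>= 0).
#' @param dist An `onset_dist` object.
#' @return Numeric vector of `n` ages in `[lo, hi)`.
#' @export
draw_onset_age <- function(n, dist) {
  stopifnot(inherits(dist, "onset_dist"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  draw1 <- function(m) {
    comp <- stats::rbinom(m, 1L, dist$w) == 1L
    u <- numeric(m)
    u[comp] <- stats::rbeta(sum(comp), dist$a1, dist$b1)
    u[!comp] <- stats::rbeta(sum(!comp), dist$a2, dist$b2)
    u * dist$max_age
  }
  if (dist$lo <= 0 && dist$hi >= dist$max_age) return(draw1(n))
  out <- numeric(0)
  accept_p <- max(.ponset_raw(dist$hi, dist) - .ponset_raw(dist$lo, dist), 1e-6)
  for (it in 1:100) {
    need <- n - length(out)
    if (need <= 0L) break
    cand <- draw1(ceiling(need / accept_p) + 16L)
    cand <- cand[cand >= dist$lo & cand < dist$hi]
    out <- c(out, cand)
  }
  if (length(out) < n) {
    stop("draw_onset_age: rejection sampling failed; window mass too small",
         call. = FALSE)
  }
  out[seq_len(n)]
}

## ---------------------------------------------------------------------------
## Default incidence trend and its joint calibration with the onset mixture.

# Latent 19-year cumulative incidence by birth year: power-shaped rise from
# p1982 to p2000, then a plateau.
.incidence_trend <- function(years, p1982 = 0.0050, p2000 = 0.0093,
                             shape = 1, rise_end = 2000) {
  frac <- pmin(pmax((years - 1982) / (rise_end - 1982), 0), 1)
  p <- p1982 + (p2000 - p1982) * frac^shape
  names(p) <- years
  p
}

# Exact birth-year distribution implied by the family process: the first
# child's year is uniform on the window and sibling k arrives after the sum
# of (k - 1) uniform{1..4} gaps, clamped to the last year.  Later cohorts are
# therefore overrepresented, which matters for any cohort-wide summary.
.birth_year_pmf <- function(sibship_dist, years) {
  ny <- length(years)
  k_max <- length(sibship_dist)
  # share of children that are the k-th born
  order_counts <- rev(cumsum(rev(sibship_dist)))
  shares <- order_counts / sum(order_counts)
  gap_pmf <- 1  # gap 0 with probability 1 for first-borns
  pmf <- numeric(ny)
  for (k in seq_len(k_max)) {
    if (k > 1L) {  # convolve with uniform{1..4}
      gp <- numeric(length(gap_pmf) + 4L)
      for (g in 1:4) {
        gp[seq_along(gap_pmf) + g] <- gp[seq_along(gap_pmf) + g] +
          gap_pmf / 4
      }
      gap_pmf <- gp
    }
    for (gi in seq_along(gap_pmf)) {
      g <- gi - 1L
      if (gap_pmf[gi] == 0) next
      yr_idx <- pmin(seq_len(ny) + g, ny)  # base year index + gap, clamped
      for (b in seq_len(ny)) {
        pmf[yr_idx[b]] <- pmf[yr_idx[b]] + shares[k] * gap_pmf[gi] / ny
      }
    }
  }
  pmf / sum(pmf)
}

# The default cohort must reproduce four printed registry facts at once:
# the 1982 and 2000 cumulative incidences (pinned by construction), the
# overall observed case fraction 20086/2928704, and the observed median onset
# age 9.9 y.  The last two depend jointly on the rise shape and the onset
# mixture weight, because children born after 2001 are right-truncated
# (followed only to age 2020 - birth year + 1).  Both are solved here
# deterministically from closed-form CDFs and the exact birth-year
# distribution of the family process; no simulation is involved.
.calibrate_default_trend <- function(overall_target = 20086 / 2928704,
                                     median_target = 9.9,
                                     admin_end_year = 2020,
                                     years = 1982:2010,
                                     sibship_dist = c(0.45, 0.40, 0.12,
                                                      0.025, 0.005)) {
  Fy <- pmin(19, admin_end_year - years + 1)
  ny <- .birth_year_pmf(sibship_dist, years)
  obj <- function(par) {
    g <- exp(par[1])
    d <- onset_age_dist(w = stats::plogis(par[2]))
    p <- .incidence_trend(years, shape = g)
    wts <- ny * p * .ponset_raw(Fy, d)
    overall <- sum(wts) / sum(ny)
    med <- stats::uniroot(function(m) {
      sum(ny * p * .ponset_raw(pmin(m, Fy), d)) / sum(wts) - 0.5
    }, interval = c(0.5, 18.5), tol = 1e-9)$root
    (1e4 * (overall - overall_target))^2 + (med - median_target)^2
  }
  fit <- stats::optim(c(log(1.5), stats::qlogis(0.45)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(shape = exp(fit$par[1]), w = stats::plogis(fit$par[2]),
       objective = fit$value)
}

# Cached per sibship distribution; deterministic.
.default_calib_env <- new.env(parent = emptyenv())
.default_calibration <- function(sibship_dist = c(0.45, 0.40, 0.12, 0.025,
                                                  0.005)) {
  key <- paste(signif(sibship_dist, 8), collapse = ",")
  if (is.null(.default_calib_env[[key]])) {
    .default_calib_env[[key]] <-
      .calibrate_default_trend(sibship_dist = unname(sibship_dist))
  }
  .default_calib_env[[key]]
}

#' Default secular trends of the maternal and perinatal covariates
#'
#' Linear trends across the cohort window: declining maternal smoking, rising
#' maternal age, BMI and education, a rising cesarean rate, and flat
#' gestational age, birth weight and infection prevalence.
#'
#' @return Named list of per-covariate trend specifications (`type` one of
#'   `"binary"`, `"normal"`, `"ordinal"`, with endpoint values).
#' @export
default_covariate_trends <- function() {
  list(
    maternal_smoking   = list(type = "binary", start = 0.30, end = 0.07),
    maternal_age       = list(type = "normal", start = 27, end = 31, sd = 5),
    maternal_bmi       = list(type = "normal", start = 23.5, end = 25.5, sd = 4),
    maternal_education = list(type = "ordinal",
                              probs_start = c(0.35, 0.40, 0.25),
                              probs_end   = c(0.15, 0.40, 0.45)),
    gestational_age    = list(type = "normal", start = 39.5, end = 39.3, sd = 1.8),
    birth_weight       = list(type = "normal", start = 3480, end = 3520, sd = 550),
    cesarean           = list(type = "binary", start = 0.11, end = 0.17),
    maternal_infection = list(type = "binary", start = 0.05, end = 0.05)
  )
}

#' Path coefficients reproducing target heritabilities at two birth years
#'
#' Builds linearly moderated path coefficients `a(y) = a0 + beta_a (y - ref)`,
#' `e(y) = e0 + beta_e (y - ref)` such that the heritability
#' `a(y)^2 / (a(y)^2 + e(y)^2)` equals `h2_start` at `year_start` and `h2_end`
#' at `year_end`, with the total liability variance standardised to 1 at
#' `ref_year`.
#'
#' @param h2_start,h2_end Target heritabilities at the two anchor years.
#' @param year_start,year_end Anchor birth years.
#' @param ref_year Standardisation year (total variance fixed at 1 there).
#' @return List with `a0`, `e0`, `beta_a`, `beta_e`, `ref_year`.
#' @export
moderated_paths <- function(h2_start, h2_end,
                            year_start = 1982, year_end = 2010,
                            ref_year = 1996) {
  stopifnot(h2_start > 0, h2_start < 1, h2_end > 0, h2_end < 1,
            year_end > year_start)
  a_s <- sqrt(h2_start); e_s <- sqrt(1 - h2_start)
  a_e <- sqrt(h2_end);   e_e <- sqrt(1 - h2_end)
  ba <- (a_e - a_s) / (year_end - year_start)
  be <- (e_e - e_s) / (year_end - year_start)
  a0 <- a_s + ba * (ref_year - year_start)
  e0 <- e_s + be * (ref_year - year_start)
  s <- 1 / sqrt(a0^2 + e0^2)  # h2(y) is scale-invariant, anchors preserved
  list(a0 = a0 * s, e0 = e0 * s, beta_a = ba * s, beta_e = be * s,
       ref_year = ref_year)
}

#' Configuration of the synthetic registry generator
#'
#' Assembles and validates the full set of study conditions used by
#' [simulate_cohort()].  The defaults emulate the Swedish childhood cohort the
#' analyses are designed for; see the package vignette for the provenance of
#' each default.
#'
#' @param n_families Number of mothers (families).  The default yields ~2.9
#'   million children under the default sibship distribution.
#' @param sibship_dist Probability vector over sibship sizes 1..5 (sums to 1).
#' @param birth_year_range Inclusive birth-year window.
#' @param birth_years Optional explicit set of permitted birth years; when
#'   given, each child's year is drawn uniformly from this set (used for
#'   two-cohort designs), otherwise families start in a uniform year and
#'   siblings follow at gaps of 1-4 years, truncated to the window.
#' @param h2 Baseline heritability at `ref_year`; shorthand for
#'   `a0 = sqrt(h2)`, `e0 = sqrt(1 - h2)`.
#' @param a0,e0 Baseline additive-genetic and non-shared-environment path
#'   coefficients; must satisfy `a0^2 + e0^2 = 1`.
#' @param beta_a,beta_e Moderation slopes of the paths per birth year
#'   (centred at `ref_year`).
#' @param ref_year Standardisation year for the liability variance.
#' @param tau0 Liability threshold, used only when
#'   `incidence_calibration = NULL`.
#' @param gamma_sex Liability mean shift for boys.
#' @param gamma_year Liability mean shift per birth year (only in the
#'   uncalibrated threshold model).
#' @param p_male Probability that a child is a boy.
#' @param incidence_calibration `"registry_trend"` for the default calibrated
#'   rise-and-plateau; a single proportion for a flat target; a named
#'   year-to-proportion vector; or `NULL` to use `tau0`/`gamma_year` directly.
#'   Targets are latent 19-year cumulative incidences.
#' @param onset_dist An [onset_age_dist()]; default is the jointly calibrated
#'   mixture (observed case median 9.9 y in the default cohort).
#' @param admin_end_year Administrative censoring year; follow-up ends at
#'   `min(19, admin_end_year - birth_year + 1)` years of age.
#' @param covariate_trends Per-covariate secular trends
#'   ([default_covariate_trends()]).
#' @param covariate_effects List with optional named numeric vectors
#'   `liability` (additive liability shifts per covariate unit) and `hazard`
#'   (log hazard ratios per covariate unit, applied on the
#'   cumulative-incidence scale).
#' @param shared_confounding Optional list `(sd, covariate, liability_load)`:
#'   a family-level normal deviate with standard deviation `sd` is added to
#'   the named covariate and, scaled by `liability_load`, to the liability.
#'   Used to emulate purely familial (confounded) exposure-outcome
#'   associations.
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return Validated object of class `generator_config`.
#' @export
generator_config <- function(n_families = 1688000,
                             sibship_dist = c(`1` = 0.45, `2` = 0.40,
                                              `3` = 0.12, `4` = 0.025,
                                              `5` = 0.005),
                             birth_year_range = c(1982L, 2010L),
                             birth_years = NULL,
                             h2 = 0.83,
                             a0 = sqrt(h2), e0 = sqrt(1 - a0^2),
                             beta_a = 0, beta_e = 0,
                             ref_year = 1996L,
                             tau0 = NULL,
                             gamma_sex = 0.05, gamma_year = 0,
                             p_male = 0.514,
                             incidence_calibration = "registry_trend",
                             onset_dist = NULL,
                             admin_end_year = 2020L,
                             covariate_trends = default_covariate_trends(),
                             covariate_effects = list(),
                             shared_confounding = NULL,
                             seed = 1L) {
  years <- if (!is.null(birth_years)) sort(unique(as.integer(birth_years)))
           else seq.int(birth_year_range[1], birth_year_range[2])
  if (is.character(incidence_calibration)) {
    stopifnot(identical(incidence_calibration, "registry_trend"))
    cal <- .default_calibration(sibship_dist)
    incidence_calibration <- .incidence_trend(years, shape = cal$shape)
    if (is.null(onset_dist)) onset_dist <- onset_age_dist(w = cal$w)
  } else if (is.numeric(incidence_calibration) &&
             length(incidence_calibration) == 1L &&
             is.null(names(incidence_calibration))) {
    incidence_calibration <- stats::setNames(
      rep(incidence_calibration, length(years)), years)
  }
  if (is.null(onset_dist)) {
    cal <- .default_calibration()
    onset_dist <- onset_age_dist(w = cal$w)
  }
  cfg <- structure(list(
    n_families = as.integer(n_families),
    sibship_dist = sibship_dist,
    birth_year_range = as.integer(birth_year_range),
    birth_years = birth_years,
    a0 = a0, e0 = e0, beta_a = beta_a, beta_e = beta_e,
    ref_year = as.integer(ref_year),
    tau0 = tau0, gamma_sex = gamma_sex, gamma_year = gamma_year,
    p_male = p_male,
    incidence_calibration = incidence_calibration,
    onset_dist = onset_dist,
    admin_end_year = as.integer(admin_end_year),
    covariate_trends = covariate_trends,
    covariate_effects = covariate_effects,
    shared_confounding = shared_confounding,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants: the sibship distribution sums to 1, the
#' baseline paths are standardised (`a0^2 + e0^2 = 1` within 1e-9), the
#' moderated paths stay admissible (`a(y) >= 0`, `e(y) > 0`) across the birth
#' window, and all incidence targets are proportions in (0, 1).
#'
#' @param config A `generator_config`.
#' @return The config, invisibly; errors describe the violated invariant.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (abs(sum(config$sibship_dist) - 1) > 1e-8 || any(config$sibship_dist < 0)) {
    stop("generator_config: sibship_dist must be a probability vector",
         call. = FALSE)
  }
  if (abs(config$a0^2 + config$e0^2 - 1) > 1e-9) {
    stop("generator_config: a0^2 + e0^2 must equal 1 at the reference year",
         call. = FALSE)
  }
  years <- .config_years(config)
  dy <- years - config$ref_year
  a_y <- config$a0 + config$beta_a * dy
  e_y <- config$e0 + config$beta_e * dy
  if (any(a_y < 0)) {
    stop("generator_config: a(y) < 0 inside the birth-year window",
         call. = FALSE)
  }
  if (any(e_y <= 0)) {
    stop("generator_config: e(y) <= 0 inside the birth-year window",
         call. = FALSE)
  }
  cal <- config$incidence_calibration
  if (!is.null(cal)) {
    if (any(cal <= 0) || any(cal >= 1)) {
      stop("generator_config: incidence targets must lie in (0, 1)",
           call. = FALSE)
    }
    if (!all(as.character(years) %in% names(cal))) {
      stop("generator_config: incidence_calibration must cover every birth year",
           call. = FALSE)
    }
  } else if (is.null(config$tau0)) {
    stop("generator_config: supply incidence_calibration or tau0",
         call. = FALSE)
  }
  if (!is.null(config$covariate_effects$hazard) && is.null(cal)) {
    stop("generator_config: hazard-scale covariate effects require the",
         " incidence-calibration path", call. = FALSE)
  }
  invisible(config)
}

.config_years <- function(config) {
  if (!is.null(config$birth_years)) sort(unique(as.integer(config$birth_years)))
  else seq.int(config$birth_year_range[1], config$birth_year_range[2])
}

#' @export
print.generator_config <- function(x, ...) {
  yrs <- .config_years(x)
  cat("Synthetic sibling-registry generator configuration\n")
  cat(sprintf("  families: %d; birth years %d-%d; admin censoring %d\n",
              x$n_families, min(yrs), max(yrs), x$admin_end_year))
  cat(sprintf("  paths at %d: a0 = %.4f, e0 = %.4f (h2 = %.3f); beta_a = %.5f, beta_e = %.5f\n",
              x$ref_year, x$a0, x$e0, x$a0^2, x$beta_a, x$beta_e))
  if (!is.null(x$incidence_calibration)) {
    p <- x$incidence_calibration
    cat(sprintf("  incidence targets: %.4f (%s) .. %.4f (%s)\n",
                p[1], names(p)[1], p[length(p)], names(p)[length(p)]))
  } else {
    cat(sprintf("  threshold model: tau0 = %.4f, gamma_year = %.5f\n",
                x$tau0, x$gamma_year))
  }
  invisible(x)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Scalar fields override the [generator_config()] defaults; `sibship_dist`
#' and `incidence_calibration` may be given as named maps.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A `generator_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (nm in c("sibship_dist", "incidence_calibration")) {
    if (!is.null(raw[[nm]]) && is.list(raw[[nm]])) {
      raw[[nm]] <- unlist(raw[[nm]])
    }
  }
  do.call(generator_config, raw)
}
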