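## Cohort simulation under the moderated AE liability-threshold model.
##
## Children within a family share one additive-genetic family deviate so that
## corr(A_i, A_j) = 0.5 for full siblings.  Liability is
##   a(y) A + e(y) E + gamma_sex * sex + covariate shifts,
## and the child is a case when liability crosses a threshold.  Thresholds are
## solved per birth year by a deterministic root-find on the normal CDF so the
## marginal crossing probability matches the configured cumulative-incidence
## target; hazard-scale covariate effects become per-child threshold shifts
## reproducing 1 - (1 - p0)^exp(x'beta).  Onset ages are drawn independently
## of liability; cases whose drawn onset exceeds their administrative
## follow-up are relabelled unaffected, mimicking registry right-truncation.

#' Draw covariate values for given birth years
#'
#' Binary covariates are Bernoulli with a linearly trending prevalence
#' (clipped to \[0, 1\]), continuous ones normal with a trending mean, ordinal
#' ones categorical with linearly interpolated level probabilities.  Uses the
#' current RNG stream.
#'
#' @param config A [generator_config()] (its `covariate_trends` are used).
#' @param birth_year Integer vector of birth years, one per child.
#' @return A `data.table` with one covariate column per configured factor.
#' @export
assign_covariates <- function(config, birth_year) {
  yr <- config$birth_year_range
  frac <- pmin(pmax((birth_year - yr[1]) / max(yr[2] - yr[1], 1), 0), 1)
  n <- length(birth_year)
  out <- vector("list", length(config$covariate_trends))
  names(out) <- names(config$covariate_trends)
  for (nm in names(config$covariate_trends)) {
    tr <- config$covariate_trends[[nm]]
    if (tr$type == "binary") {
      p <- pmin(pmax(tr$start + (tr$end - tr$start) * frac, 0), 1)
      out[[nm]] <- stats::rbinom(n, 1L, p)
    } else if (tr$type == "normal") {
      mu <- tr$start + (tr$end - tr$start) * frac
      out[[nm]] <- stats::rnorm(n, mu, tr$sd)
    } else if (tr$type == "ordinal") {
      k <- length(tr$probs_start)
      pm <- outer(frac, tr$probs_end - tr$probs_start) +
        matrix(tr$probs_start, n, k, byrow = TRUE)
      cum <- t(apply(pm, 1L, cumsum))
      u <- stats::runif(n) * cum[, k]
      out[[nm]] <- 1L + rowSums(u > cum[, -k, drop = FALSE])
    } else {
      stop("assign_covariates: unknown trend type '", tr$type, "'",
           call. = FALSE)
    }
  }
  data.table::setDT(out)
  out[]
}

# Per-year threshold solving mean_i P(case_i) = target, over the realised
# mean-shift / hazard-multiplier groups.  mu and r are the per-child liability
# mean shifts and hazard multipliers within one birth year; sdV the liability
# SD for that year.
.solve_year_threshold <- function(mu, r, sdV, target) {
  grp <- data.table::data.table(mu = mu, r = r)[, .N, by = c("mu", "r")]
  f <- function(tau) {
    q <- stats::pnorm((tau - grp$mu) / sdV, lower.tail = FALSE)
    sum(grp$N * (1 - (1 - q)^grp$r)) / length(mu) - target
  }
  lo <- min(mu) - 10 * sdV
  hi <- max(mu) + 10 * sdV
  stats::uniroot(f, interval = c(lo, hi), tol = 1e-12)$root
}

#' Simulate a registry-like cohort of sibling families
#'
#' Generates one row per child: identifiers, sex, birth year, birth order,
#' trending covariates, outcome status, onset age and administrative
#' follow-up, under the liability model described in the package vignette.
#' Identical `config` and `seed` give identical output.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to the seed stored in the config.
#' @param debug_latent If `TRUE`, also emit the latent `liability_a` and
#'   `liability_e` components (generator diagnostics only).
#' @return A `data.table` with one `ChildRecord` row per child.
#' @export
simulate_cohort <- function(config, seed = config$seed, debug_latent = FALSE) {
  validate_config(config)
  cols <- c("child_id", "family_id", "sex", "birth_year", "birth_order",
            names(config$covariate_trends), "t1d", "onset_age",
            "followup_end_age")
  if (config$n_families <= 0L) {
    empty <- data.table::as.data.table(
      stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(empty)
  }
  set.seed(seed)
  nf <- config$n_families
  sizes <- sample.int(length(config$sibship_dist), nf, replace = TRUE,
                      prob = config$sibship_dist)
  n <- sum(sizes)
  fam <- rep.int(seq_len(nf), sizes)
  birth_order <- sequence(sizes)

  yr <- config$birth_year_range
  if (!is.null(config$birth_years)) {
    bys <- as.integer(config$birth_years)
    by <- bys[sample.int(length(bys), n, replace = TRUE)]
  } else {
    base <- sample.int(yr[2] - yr[1] + 1L, nf, replace = TRUE) + yr[1] - 1L
    gap <- sample.int(4L, n, replace = TRUE)
    gap[birth_order == 1L] <- 0L
    cg <- cumsum(gap)
    first <- cumsum(sizes) - sizes + 1L
    cg <- cg - rep.int(cg[first], sizes)
    by <- pmin(rep.int(base, sizes) + cg, yr[2])
  }

  sex <- stats::rbinom(n, 1L, config$p_male)
  A_f <- stats::rnorm(nf)
  A <- sqrt(0.5) * rep.int(A_f, sizes) + sqrt(0.5) * stats::rnorm(n)
  E <- stats::rnorm(n)
  cov <- assign_covariates(config, by)

  # family-level confounder: enters a covariate and (scaled) the liability
  conf_shift <- 0
  if (!is.null(config$shared_confounding) &&
      isTRUE(config$shared_confounding$sd > 0)) {
    sc <- config$shared_confounding
    W <- rep.int(stats::rnorm(nf, 0, sc$sd), sizes)
    data.table::set(cov, j = sc$covariate, value = cov[[sc$covariate]] + W)
    conf_shift <- sc$liability_load * W
  }

  dy <- by - config$ref_year
  a_y <- config$a0 + config$beta_a * dy
  e_y <- config$e0 + config$beta_e * dy
  sdV <- sqrt(a_y^2 + e_y^2)

  mu <- config$gamma_sex * sex + conf_shift
  eff <- config$covariate_effects
  if (!is.null(eff$liability)) {
    for (nm in names(eff$liability)) {
      mu <- mu + eff$liability[[nm]] * .effect_column(cov, nm, birth_order)
    }
  }
  logr <- 0
  if (!is.null(eff$hazard)) {
    for (nm in names(eff$hazard)) {
      logr <- logr + eff$hazard[[nm]] * .effect_column(cov, nm, birth_order)
    }
  }
  r <- exp(logr)

  liab_ae <- a_y * A + e_y * E
  if (!is.null(config$incidence_calibration)) {
    tau_child <- numeric(n)
    cal <- config$incidence_calibration
    plain <- length(r) == 1L && r[1] == 1
    for (y in unique(by)) {
      idx <- which(by == y)
      target <- cal[[as.character(y)]]
      sdy <- sdV[idx[1]]
      mu_y <- if (length(mu) == 1L) rep(mu, length(idx)) else mu[idx]
      tau <- .solve_year_threshold(mu_y, if (plain) rep(1, length(idx))
                                         else r[idx], sdy, target)
      if (plain) {
        tau_child[idx] <- tau
      } else {
        q0 <- stats::pnorm((tau - mu_y) / sdy, lower.tail = FALSE)
        p_i <- 1 - (1 - q0)^r[idx]
        tau_child[idx] <- mu_y + sdy * stats::qnorm(p_i, lower.tail = FALSE)
      }
    }
    case <- (liab_ae + mu) > tau_child
  } else {
    mu <- mu + config$gamma_year * dy
    case <- (liab_ae + mu) > config$tau0
  }

  followup <- pmin(19, config$admin_end_year - by + 1)
  onset <- rep(NA_real_, n)
  onset[case] <- draw_onset_age(sum(case), config$onset_dist)
  t1d <- case & !is.na(onset) & onset < followup
  onset[!t1d] <- NA_real_

  out <- data.table::data.table(
    child_id = seq_len(n), family_id = fam, sex = sex, birth_year = by,
    birth_order = birth_order)
  out <- cbind(out, cov)
  out[, `:=`(t1d = as.integer(t1d), onset_age = onset,
             followup_end_age = as.numeric(followup))]
  if (debug_latent) {
    out[, `:=`(liability_a = a_y * A, liability_e = e_y * E)]
  }
  out[]
}

# covariates usable in effect hooks: any generated column plus birth_order
.effect_column <- function(cov, nm, birth_order) {
  if (nm == "birth_order") return(birth_order)
  if (!nm %in% names(cov)) {
    stop("covariate effect refers to unknown covariate '", nm, "'",
         call. = FALSE)
  }
  cov[[nm]]
}

#' Write / read a cohort as CSV
#'
#' One row per child, fixed header, UTF-8, `.` decimal separator.  `.gz`
#' suffixes are handled transparently.
#'
#' @param cohort A cohort `data.table` from [simulate_cohort()].
#' @param path Output (input) file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data.table::fread(path)
}
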