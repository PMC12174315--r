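## Moderated AE liability-threshold model for full-sibling pairs.
##
## Liability of a child born in year y is a(y) A + e(y) E with
##   a(y) = a0 + beta_a (y - ref),   e(y) = e0 + beta_e (y - ref),
## standardised so a0^2 + e0^2 = 1 at the reference year; full siblings share
## half of A, so the cross-sibling liability covariance of a pair born in
## years (y1, y2) is 0.5 a(y1) a(y2).  Sex and birth year shift the liability
## mean (equivalently, move the threshold).  The four outcome probabilities
## of a pair follow from the bivariate-normal orthant kernel, and the model
## is fitted by maximising the cell-weighted log-likelihood.
##
## Model specifications: model1 frees both moderation slopes, model2 only the
## genetic slope, model3 only the environmental slope, model4 neither.

# internal birth-year scaling for optimiser conditioning
.YEAR_SCALE <- 14

#' Parameters of the moderated AE liability model
#'
#' @param a0,e0 Baseline path coefficients at `ref_year`
#'   (`a0^2 + e0^2 = 1`).
#' @param beta_a,beta_e Moderation slopes of the paths per birth year.
#' @param tau0 Liability threshold at the reference covariate values.
#' @param gamma_sex,gamma_year Liability mean shifts for boys and per birth
#'   year (centred at `ref_year`).
#' @param ref_year Standardisation year.
#' @return Object of class `moderated_ae_params`.
#' @export
moderated_ae_params <- function(a0, e0, beta_a = 0, beta_e = 0, tau0 = 2.45,
                                gamma_sex = 0, gamma_year = 0,
                                ref_year = 1996) {
  if (abs(a0^2 + e0^2 - 1) > 1e-9) {
    stop("moderated_ae_params: a0^2 + e0^2 must equal 1", call. = FALSE)
  }
  structure(list(a0 = a0, e0 = e0, beta_a = beta_a, beta_e = beta_e,
                 tau0 = tau0, gamma_sex = gamma_sex, gamma_year = gamma_year,
                 ref_year = ref_year),
            class = "moderated_ae_params")
}

#' @export
print.moderated_ae_params <- function(x, ...) {
  cat(sprintf(
    "Moderated AE parameters (ref %d): a0 = %.4f, e0 = %.4f, beta_a = %.3e, beta_e = %.3e\n",
    x$ref_year, x$a0, x$e0, x$beta_a, x$beta_e))
  cat(sprintf("  threshold tau0 = %.4f; gamma_sex = %.4f; gamma_year = %.3e\n",
              x$tau0, x$gamma_sex, x$gamma_year))
  cat(sprintf("  h2 at ref year: %.4f\n", x$a0^2))
  invisible(x)
}

# paths at a vector of birth years; variance_linear switches to moderation on
# the variance scale, a(y)^2 = a0^2 + beta_a (y - ref)
.paths_at <- function(params, years, variance_linear = FALSE) {
  dy <- years - params$ref_year
  if (variance_linear) {
    a2 <- params$a0^2 + params$beta_a * dy
    e2 <- params$e0^2 + params$beta_e * dy
    if (any(a2 < 0) || any(e2 <= 0)) return(NULL)
    list(a = sqrt(a2), e = sqrt(e2))
  } else {
    a <- params$a0 + params$beta_a * dy
    e <- params$e0 + params$beta_e * dy
    if (any(a < 0) || any(e <= 0)) return(NULL)
    list(a = a, e = e)
  }
}

#' Outcome-pattern probabilities for sibling-pair cells
#'
#' For each cell, the marginal liability of member i has mean
#' `gamma_sex sex_i + gamma_year (y_i - ref)` and variance
#' `a(y_i)^2 + e(y_i)^2`; the cross-covariance is `0.5 a(y_1) a(y_2)`.
#' Returns the probability of each cell's observed `(y1, y2)` pattern; the
#' four patterns of any covariate combination sum to 1.
#'
#' @param params A [moderated_ae_params()].
#' @param cells A `pair_cells` table (the `count` column is ignored).
#' @param variance_linear Moderate variances instead of paths (the
#'   alternative functional form).
#' @return Numeric vector of probabilities, one per cell row.
#' @export
pair_probability <- function(params, cells, variance_linear = FALSE) {
  p <- .cell_probs(params, cells, variance_linear)
  if (is.null(p)) {
    stop("pair_probability: parameters give an inadmissible liability",
         " variance inside the data's birth-year range", call. = FALSE)
  }
  p
}

.cell_probs <- function(params, cells, variance_linear = FALSE) {
  p1v <- .paths_at(params, cells$by1, variance_linear)
  p2v <- .paths_at(params, cells$by2, variance_linear)
  if (is.null(p1v) || is.null(p2v)) return(NULL)
  v1 <- p1v$a^2 + p1v$e^2
  v2 <- p2v$a^2 + p2v$e^2
  mu1 <- params$gamma_sex * cells$sex1 +
    params$gamma_year * (cells$by1 - params$ref_year)
  mu2 <- params$gamma_sex * cells$sex2 +
    params$gamma_year * (cells$by2 - params$ref_year)
  t1 <- (params$tau0 - mu1) / sqrt(v1)
  t2 <- (params$tau0 - mu2) / sqrt(v2)
  rho <- 0.5 * p1v$a * p2v$a / sqrt(v1 * v2)
  p11 <- bvn_orthant(t1, t2, rho)
  p1 <- stats::pnorm(t1, lower.tail = FALSE)
  p2 <- stats::pnorm(t2, lower.tail = FALSE)
  ifelse(cells$y1 == 1L & cells$y2 == 1L, p11,
  ifelse(cells$y1 == 1L, p1 - p11,
  ifelse(cells$y2 == 1L, p2 - p11, 1 - p1 - p2 + p11)))
}

#' Cell-weighted log-likelihood of the pair model
#'
#' `sum(count * log(prob))` over the cells; equals the pair-by-pair sum on
#' uncollapsed data, at a cost that depends only on the number of distinct
#' cells.  Returns `-Inf` (never an error) when any cell probability is
#' non-positive or the parameters are inadmissible, so optimisers simply
#' reject such points.
#'
#' @inheritParams pair_probability
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
pair_loglik <- function(params, cells, variance_linear = FALSE) {
  stopifnot(nrow(cells) > 0)
  p <- .cell_probs(params, cells, variance_linear)
  if (is.null(p) || any(p <= 0) || anyNA(p)) return(-Inf)
  sum(cells$count * log(p))
}

## -- fitting ----------------------------------------------------------------

# free-parameter layout for each model specification
.model_slopes <- function(model) {
  switch(model,
         model1 = c(TRUE, TRUE), model2 = c(TRUE, FALSE),
         model3 = c(FALSE, TRUE), model4 = c(FALSE, FALSE),
         stop("unknown model spec '", model, "'", call. = FALSE))
}

.par_to_params <- function(par, layout, ref_year) {
  i <- 1L
  th <- par[i]; i <- i + 1L
  ba <- 0; be <- 0
  if (layout$slopes[1]) { ba <- par[i] / .YEAR_SCALE; i <- i + 1L }
  if (layout$slopes[2]) { be <- par[i] / .YEAR_SCALE; i <- i + 1L }
  tau <- par[i]; i <- i + 1L
  gs <- 0; gy <- 0
  if (layout$has_sex) { gs <- par[i]; i <- i + 1L }
  if (layout$has_year) { gy <- par[i] / .YEAR_SCALE }
  moderated_ae_params(a0 = sin(th), e0 = cos(th),
                      beta_a = ba, beta_e = be, tau0 = tau,
                      gamma_sex = gs, gamma_year = gy, ref_year = ref_year)
}

#' Fit the AE liability-threshold model to sibling-pair cells
#'
#' Maximises the cell log-likelihood over the free parameters of the chosen
#' specification, subject to `a0^2 + e0^2 = 1` (parameterised as
#' `a0 = sin(theta)`, `e0 = cos(theta)`).  Three deterministic starting
#' values for the baseline heritability are refined by Nelder-Mead and then
#' polished with BFGS; the threshold regression includes sex and (centred)
#' birth year whenever the cells vary in them.
#'
#' @param cells A `pair_cells` table from [make_sibling_pairs()].
#' @param model `"model1"` (both slopes free), `"model2"` (genetic slope),
#'   `"model3"` (environment slope) or `"model4"` (no moderation).
#' @param ref_year Standardisation year (total variance 1 there).
#' @param variance_linear Use the variance-scale moderation variant.
#' @param starts Baseline-heritability starting values.
#' @param start_params Optional `moderated_ae_params` used as the single
#'   starting point (bootstrap refits).
#' @return An object of class `ae_fit`: `params`, `loglik`, `n_free_params`,
#'   `aic`, `converged`, `n_pairs`, `model`, plus a data fingerprint.
#' @export
fit_ae <- function(cells, model = c("model4", "model1", "model2", "model3"),
                   ref_year = 1996, variance_linear = FALSE,
                   starts = c(0.4, 0.7, 0.9), start_params = NULL) {
  model <- match.arg(model)
  stopifnot(nrow(cells) > 0)
  n_aff_pairs <- sum(cells$count[cells$y1 + cells$y2 > 0])
  if (n_aff_pairs == 0) {
    stop("fit_ae: no pairs with an affected member; the AE model is not",
         " identifiable", call. = FALSE)
  }
  layout <- list(
    slopes = .model_slopes(model),
    has_sex = length(unique(c(cells$sex1, cells$sex2))) > 1L,
    has_year = length(unique(c(cells$by1, cells$by2))) > 1L)

  negll <- function(par) {
    ll <- pair_loglik(.par_to_params(par, layout, ref_year), cells,
                      variance_linear)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  n_total <- sum(cells$count)
  phat <- sum(cells$count * (cells$y1 + cells$y2)) / (2 * n_total)
  tau_start <- stats::qnorm(phat, lower.tail = FALSE)

  build_start <- function(h0) {
    par <- asin(sqrt(h0))
    if (layout$slopes[1]) par <- c(par, 0)
    if (layout$slopes[2]) par <- c(par, 0)
    par <- c(par, tau_start)
    if (layout$has_sex) par <- c(par, 0)
    if (layout$has_year) par <- c(par, 0)
    par
  }
  start_list <- lapply(starts, build_start)
  if (!is.null(start_params)) {
    p0 <- start_params
    par <- asin(min(max(p0$a0, 1e-6), 1 - 1e-9))
    if (layout$slopes[1]) par <- c(par, p0$beta_a * .YEAR_SCALE)
    if (layout$slopes[2]) par <- c(par, p0$beta_e * .YEAR_SCALE)
    par <- c(par, p0$tau0)
    if (layout$has_sex) par <- c(par, p0$gamma_sex)
    if (layout$has_year) par <- c(par, p0$gamma_year * .YEAR_SCALE)
    start_list <- list(par)
  }

  best <- NULL
  for (par0 in start_list) {
    nm <- stats::optim(par0, negll, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-10))
    bf <- tryCatch(
      stats::optim(nm$par, negll, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-10)),
      error = function(e) nm)
    cand <- if (bf$value <= nm$value) bf else nm
    cand$nm_value <- nm$value
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  params <- .par_to_params(best$par, layout, ref_year)
  # canonical sign: a0 >= 0 (sin(theta) may come out negative; h2 unchanged)
  if (params$a0 < 0) {
    params$a0 <- -params$a0
    params$beta_a <- -params$beta_a
  }
  if (params$e0 < 0) {
    params$e0 <- -params$e0
    params$beta_e <- -params$beta_e
  }
  k <- 1L + sum(layout$slopes) + 1L + layout$has_sex + layout$has_year
  ll <- -best$value
  converged <- is.finite(ll) &&
    (abs(best$nm_value - best$value) < 1e-4 * (1 + abs(best$value)))
  structure(list(
    model = model, params = params, loglik = ll,
    n_free_params = as.integer(k), aic = 2 * k - 2 * ll,
    converged = converged, n_pairs = attr(cells, "n_pairs"),
    variance_linear = variance_linear,
    fingerprint = .cells_fingerprint(cells)),
    class = "ae_fit")
}

.cells_fingerprint <- function(cells) {
  c(n_cells = nrow(cells), n = sum(cells$count),
    chk = sum(cells$count * (1 + cells$y1 + 2 * cells$y2)) +
      sum(cells$by1 + cells$by2))
}

#' @export
print.ae_fit <- function(x, ...) {
  cat(sprintf("AE liability-threshold fit (%s%s)\n", x$model,
              if (x$variance_linear) ", variance-linear moderation" else ""))
  cat(sprintf("  pairs: %s; logLik = %.3f; AIC = %.3f; free params = %d%s\n",
              format(x$n_pairs, big.mark = ","), x$loglik, x$aic,
              x$n_free_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  h2(ref) = %.4f; e2(ref) = %.4f\n",
              x$params$a0^2, x$params$e0^2))
  invisible(x)
}

#' Heritability and non-shared-environment proportions by birth year
#'
#' `h2(y) = a(y)^2 / (a(y)^2 + e(y)^2)` and its complement.
#'
#' @param params A `moderated_ae_params` or an `ae_fit`.
#' @param years Birth years at which to evaluate the curve.
#' @param variance_linear Use the variance-scale moderation variant.
#' @return `data.frame` of class `heritability_curve` with columns
#'   `birth_year`, `h2`, `e2`.
#' @export
h2_curve <- function(params, years, variance_linear = FALSE) {
  if (inherits(params, "ae_fit")) {
    variance_linear <- params$variance_linear
    params <- params$params
  }
  p <- .paths_at(params, years, variance_linear)
  if (is.null(p)) {
    stop("h2_curve: parameters inadmissible at the requested years",
         call. = FALSE)
  }
  h2 <- p$a^2 / (p$a^2 + p$e^2)
  structure(data.frame(birth_year = years, h2 = h2, e2 = 1 - h2),
            class = c("heritability_curve", "data.frame"))
}

#' Compare nested AE model specifications
#'
#' Reports -2 logLik, AIC, and likelihood-ratio tests for the nested pairs
#' (model4 in model2/model3, model2/model3 in model1, model4 in model1) with
#' degrees of freedom equal to the number of freed moderation slopes.  All
#' fits must come from the same cells.
#'
#' @param fits List of `ae_fit` objects.
#' @return `data.frame` with one row per fit (`minus2LL`, `aic`) and
#'   attribute `"lrt"` holding the test table.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, TRUE, "ae_fit")))
  fp <- vapply(fits, function(f) f$fingerprint, numeric(3))
  if (any(apply(fp, 1L, function(z) max(abs(z - z[1]))) > 0)) {
    stop("compare_models: fits were produced from different data",
         call. = FALSE)
  }
  names(fits) <- vapply(fits, `[[`, "", "model")
  tab <- data.frame(
    model = names(fits),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    minus2LL = -2 * vapply(fits, `[[`, 0, "loglik"),
    n_free_params = vapply(fits, `[[`, 0L, "n_free_params"),
    aic = vapply(fits, `[[`, 0, "aic"),
    row.names = NULL)
  nested <- list(c("model4", "model2"), c("model4", "model3"),
                 c("model2", "model1"), c("model3", "model1"),
                 c("model4", "model1"))
  lrt <- do.call(rbind, lapply(nested, function(pr) {
    if (!all(pr %in% names(fits))) return(NULL)
    f0 <- fits[[pr[1]]]; f1 <- fits[[pr[2]]]
    df <- f1$n_free_params - f0$n_free_params
    stat <- max(0, 2 * (f1$loglik - f0$loglik))
    data.frame(null = pr[1], alternative = pr[2], df = df, lrt = stat,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }))
  attr(tab, "lrt") <- lrt
  tab
}

#' Family-bootstrap confidence intervals for the heritability curve
#'
#' Resamples whole families with replacement (as many as in the original
#' cohort), re-forms the sibling pairs, refits the model starting from the
#' full-data optimum, and reports percentile intervals of the year-specific
#' heritability and non-shared-environment proportions.  Years whose interval
#' is wider than 0.3 are flagged as unstable (estimates at the extremes of
#' the birth window typically are).
#'
#' @param cohort A cohort `data.table`.
#' @param model Model specification passed to [fit_ae()].
#' @param years Years at which to evaluate the curve.
#' @param B Number of bootstrap resamples (>= 2; the registry analyses use
#'   1000).
#' @param seed RNG seed (resampling is seed-deterministic).
#' @param mode,outcome Passed to [make_sibling_pairs()].
#' @param ref_year,variance_linear Passed to [fit_ae()].
#' @return A `heritability_curve` data frame with `ci_low`, `ci_high`,
#'   `e2_ci_low`, `e2_ci_high` and `unstable` columns; the full-data fit is
#'   attached as attribute `"fit"`.
#' @export
bootstrap_ci <- function(cohort, model = "model1", years = NULL, B = 1000,
                         seed = 1, mode = "all_pairs", outcome = "t1d",
                         ref_year = 1996, variance_linear = FALSE) {
  if (B < 2) stop("bootstrap_ci: B must be at least 2", call. = FALSE)
  dt <- data.table::as.data.table(cohort)
  if (is.null(years)) years <- sort(unique(dt$birth_year))
  cells <- make_sibling_pairs(dt, mode = mode, outcome = outcome)
  fit0 <- fit_ae(cells, model = model, ref_year = ref_year,
                 variance_linear = variance_linear)
  fams <- unique(dt$family_id)
  nfam <- length(fams)
  data.table::setkey(dt, family_id)
  set.seed(seed)
  h2b <- matrix(NA_real_, B, length(years))
  for (b in seq_len(B)) {
    draw <- data.table::data.table(
      family_id = fams[sample.int(nfam, nfam, replace = TRUE)],
      .bid = seq_len(nfam))
    res <- dt[draw, on = "family_id", allow.cartesian = TRUE]
    res[, family_id := .bid]
    cells_b <- make_sibling_pairs(res, mode = mode, outcome = outcome)
    fit_b <- tryCatch(
      fit_ae(cells_b, model = model, ref_year = ref_year,
             variance_linear = variance_linear, start_params = fit0$params),
      error = function(e) NULL)
    if (!is.null(fit_b)) h2b[b, ] <- h2_curve(fit_b, years)$h2
  }
  point <- h2_curve(fit0, years)
  qs <- apply(h2b, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  point$ci_low <- qs[1, ]
  point$ci_high <- qs[2, ]
  point$e2_ci_low <- 1 - qs[2, ]
  point$e2_ci_high <- 1 - qs[1, ]
  point$unstable <- (point$ci_high - point$ci_low) > 0.3
  attr(point, "fit") <- fit0
  attr(point, "B") <- B
  point
}
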