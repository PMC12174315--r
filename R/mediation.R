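## Survival-setting causal mediation for the birth-cohort incidence rise.
##
## The exposure is the birth cohort (year1 vs year0), the mediator a single
## environmental factor, and the outcome scale the cumulative incidence
## before the horizon age.  A proportional-hazards model with the cohort
## indicator, the factor and the adjustment covariates is fitted; the Breslow
## baseline cumulative hazard turns linear predictors into model-implied
## cumulative incidences.  With G_m the empirical factor distribution of
## cohort m (covariates held at their observed values in the pooled sample),
##   F(a, G_m) = mean over C, average over M ~ G_m of 1 - exp(-H0 e^{lp}),
##   total = F(1, G1) - F(0, G0),
##   nie   = F(1, G1) - F(1, G0)   (via the factor's changing distribution),
##   nde   = F(1, G0) - F(0, G0)   (everything else),
## so nie + nde = total exactly, before any rounding.  All three are
## reported per 10,000 children.

#' Decompose the cohort incidence rise into natural direct/indirect effects
#'
#' @param records Survival records ([as_survival_records()]).
#' @param factor Mediator column name.
#' @param year0,year1 Baseline and comparison birth cohorts.
#' @param horizon_age Cumulative-incidence horizon (age, years); capped at
#'   the shortest administrative follow-up of the two cohorts.
#' @param adjustment Covariates entering the hazard model.
#' @param mediator_grid_size Number of quantile points used to represent a
#'   continuous mediator distribution (categorical mediators use their
#'   observed levels).
#' @return Object of class `mediation_result`: `factor`, `year0`, `year1`,
#'   `total_increase`, `nie`, `nde` (per 10,000), `proportion_explained`
#'   (percent), `n_used`.
#' @export
mediate_trend <- function(records, factor, year0 = 1982, year1 = 2000,
                          horizon_age = 19,
                          adjustment = c("sex", "maternal_age",
                                         "maternal_education",
                                         "maternal_bmi", "maternal_smoking"),
                          mediator_grid_size = 100) {
  dt <- data.table::as.data.table(records)
  keep <- dt$birth_year %in% c(year0, year1)
  dt <- dt[keep]
  adjustment <- setdiff(adjustment, factor)
  adjustment <- intersect(adjustment, names(dt))
  use <- stats::complete.cases(dt[, c(factor, adjustment, "exit_age",
                                      "event"), with = FALSE])
  dt <- dt[use]
  if (!all(c(year0, year1) %in% dt$birth_year) || sum(dt$event) == 0) {
    stop("mediate_trend: both cohorts must be present with events",
         call. = FALSE)
  }
  dt[, .cohort := as.integer(birth_year == year1)]
  dt[, .m := dt[[factor]]]
  horizon <- min(horizon_age, max(dt$exit_age))

  form <- stats::as.formula(paste(
    "survival::Surv(exit_age, event) ~ .cohort + .m +",
    paste(adjustment, collapse = " + ")))
  fit <- survival::coxph(form, data = dt, ties = "breslow")
  if (any(is.na(stats::coef(fit)))) {
    stop("mediate_trend: hazard model did not converge", call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- max(0, utils::tail(bh$hazard[bh$time <= horizon], 1L))

  cf <- stats::coef(fit)
  b_cohort <- cf[".cohort"]
  m_names <- grep("^\\.m", names(cf), value = TRUE)
  # linear-predictor pieces: covariates (per pooled child), mediator values
  X_adj <- stats::model.matrix(
    stats::as.formula(paste("~", paste(adjustment, collapse = " + "))),
    data = dt)[, -1, drop = FALSE]
  lp_adj <- as.vector(X_adj %*% cf[colnames(X_adj)])

  # mediator representation: observed levels for discrete, quantile grid for
  # continuous; weights are the cohort-specific empirical frequencies
  m_rep <- function(m_values) {
    if (is.numeric(m_values) && length(unique(m_values)) > 12L) {
      probs <- (seq_len(mediator_grid_size) - 0.5) / mediator_grid_size
      vals <- stats::quantile(m_values, probs, names = FALSE, type = 8)
      list(vals = vals, w = rep(1 / length(vals), length(vals)))
    } else {
      tab <- table(m_values)
      list(vals = type.convert(names(tab), as.is = TRUE),
           w = as.vector(tab) / length(m_values))
    }
  }
  lp_of_m <- function(vals) {
    if (length(m_names) == 1L && m_names == ".m") {
      cf[".m"] * as.numeric(vals)
    } else {  # factor mediator: coefficient per non-reference level
      out <- numeric(length(vals))
      for (i in seq_along(vals)) {
        nm <- paste0(".m", vals[i])
        out[i] <- if (nm %in% m_names) cf[nm] else 0
      }
      out
    }
  }

  Fam <- function(a, grid) {
    lp_m <- lp_of_m(grid$vals)
    acc <- 0
    for (j in seq_along(lp_m)) {
      risk <- 1 - exp(-H0 * exp(b_cohort * a + lp_m[j] + lp_adj))
      acc <- acc + grid$w[j] * mean(risk)
    }
    acc
  }
  g0 <- m_rep(dt$.m[dt$.cohort == 0L])
  g1 <- m_rep(dt$.m[dt$.cohort == 1L])

  F11 <- Fam(1, g1)
  F10 <- Fam(1, g0)
  F00 <- Fam(0, g0)
  total <- (F11 - F00) * 1e4
  nie <- (F11 - F10) * 1e4
  nde <- (F10 - F00) * 1e4
  structure(list(
    factor = factor, year0 = year0, year1 = year1,
    total_increase = total, nie = nie, nde = nde,
    proportion_explained = 100 * nie / total,
    n_used = nrow(dt), horizon_age = horizon),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation of the %d -> %d cumulative-incidence rise via %s\n",
    x$year0, x$year1, x$factor))
  cat(sprintf(
    "  total %.1f per 10,000 = NIE %.2f + NDE %.2f; proportion explained %.1f%%\n",
    x$total_increase, x$nie, x$nde, x$proportion_explained))
  invisible(x)
}

#' Assemble a decomposition row from its components
#'
#' The reporting identity of the decomposition: `total = nie + nde` and
#' `proportion = 100 nie / total`.  Useful for checking published tables
#' whose columns were rounded independently.
#'
#' @param nie,nde Natural indirect and direct components (per 10,000).
#' @return List with `total_increase`, `nie`, `nde`, `proportion_explained`.
#' @export
mediation_row <- function(nie, nde) {
  total <- nie + nde
  list(total_increase = total, nie = nie, nde = nde,
       proportion_explained = 100 * nie / total)
}

#' Summary-level contribution of a factor to the incidence rise
#'
#' For a factor observed only as cohort prevalences and a published
#' relative-risk range (childhood overweight/obesity), the indirect effect
#' at relative risk `r` is
#' `baseline_incidence (r - 1) (prevalence1 - prevalence0) /
#'  (1 + prevalence0 (r - 1))`,
#' evaluated at both ends of the range.
#'
#' @param total_increase Total incidence rise, per 10,000 children.
#' @param prevalence0,prevalence1 Factor prevalences in the two cohorts.
#' @param rr_range Length-2 vector of published relative risks (low, high).
#' @param baseline_incidence Baseline cumulative incidence per 10,000.
#' @return Object of class `summary_contribution` with `nie_range`
#'   (per 10,000) and `proportion_range` (percent), both ordered.
#' @export
summary_contribution <- function(total_increase, prevalence0, prevalence1,
                                 rr_range, baseline_incidence) {
  if (total_increase <= 0) {
    stop("summary_contribution: total_increase must be positive",
         call. = FALSE)
  }
  stopifnot(prevalence0 >= 0, prevalence0 <= 1,
            prevalence1 >= 0, prevalence1 <= 1, all(rr_range > 0))
  nie <- vapply(rr_range, function(r) {
    baseline_incidence * (r - 1) * (prevalence1 - prevalence0) /
      (1 + prevalence0 * (r - 1))
  }, 0)
  nie <- sort(nie)
  structure(list(
    total_increase = total_increase,
    prevalence0 = prevalence0, prevalence1 = prevalence1,
    rr_range = sort(rr_range), nie_range = nie,
    proportion_range = 100 * nie / total_increase),
    class = "summary_contribution")
}

#' @export
print.summary_contribution <- function(x, ...) {
  cat(sprintf(
    "Summary-level contribution: NIE %.2f-%.2f per 10,000 (%.1f-%.1f%% of %.1f)\n",
    x$nie_range[1], x$nie_range[2], x$proportion_range[1],
    x$proportion_range[2], x$total_increase))
  invisible(x)
}
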