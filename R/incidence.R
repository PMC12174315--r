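## Birth-cohort incidence trend: Kaplan-Meier cumulative incidence by birth
## year and Cox proportional-hazards HRs for each birth year against the
## reference cohort, with attained age as the time scale, sex adjustment and
## mother-clustered robust (sandwich) standard errors.

#' Convert a cohort into survival records
#'
#' One record per child with entry at age 0 and exit at the onset age (cases)
#' or the administrative follow-up end (non-cases).
#'
#' @param cohort A cohort `data.table` from [simulate_cohort()] (or a CSV
#'   read back with [read_cohort()]).
#' @return A `data.table` with `child_id`, `family_id`, `exit_age`, `event`,
#'   `birth_year`, `sex` and any covariate columns carried along.
#' @export
as_survival_records <- function(cohort) {
  dt <- data.table::as.data.table(cohort)
  stopifnot(all(c("t1d", "onset_age", "followup_end_age") %in% names(dt)))
  dt <- data.table::copy(dt)
  dt[, exit_age := ifelse(t1d == 1L, onset_age, followup_end_age)]
  dt[, event := as.integer(t1d)]
  dt[, c("t1d", "onset_age", "followup_end_age") := NULL]
  if (any(dt$exit_age <= 0 | dt$exit_age > 19)) {
    stop("as_survival_records: exit ages must lie in (0, 19]", call. = FALSE)
  }
  dt[]
}

#' Kaplan-Meier cumulative incidence before a horizon age
#'
#' `1 - S(horizon)` from the Kaplan-Meier estimator, with a Greenwood-based
#' 95% CI on the plain scale (estimate +/- 1.96 standard errors).  If nobody
#' remains at risk before the horizon, the estimate at the last observed age
#' is returned with `truncated = TRUE`, alongside a warning.
#'
#' @param records Survival records ([as_survival_records()]).
#' @param birth_year Optional single birth year to subset to.
#' @param horizon_age Horizon in years of age (default 19).
#' @return One-row `data.frame`: `birth_year`, `age`, `estimate`, `ci_low`,
#'   `ci_high`, `n`, `events`, `truncated`.
#' @export
cumulative_incidence <- function(records, birth_year = NULL,
                                 horizon_age = 19) {
  dt <- data.table::as.data.table(records)
  if (!is.null(birth_year)) {
    keep <- dt$birth_year == birth_year
    dt <- dt[keep]
  }
  if (nrow(dt) == 0L) {
    stop("cumulative_incidence: no records for this birth year",
         call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(exit_age, event) ~ 1, data = dt,
                           conf.type = "plain")
  last <- max(fit$time)
  at <- min(horizon_age, last)
  truncated <- last < horizon_age
  if (truncated) {
    warning("cumulative_incidence: follow-up ends at age ",
            signif(last, 4), ", before the requested horizon", call. = FALSE)
  }
  s <- summary(fit, times = at, extend = TRUE)
  est <- 1 - s$surv
  se <- s$std.err
  data.frame(
    birth_year = if (is.null(birth_year)) NA_integer_ else birth_year,
    age = at, estimate = est,
    ci_low = max(0, est - 1.96 * se), ci_high = min(1, est + 1.96 * se),
    n = nrow(dt), events = sum(dt$event), truncated = truncated)
}

#' Kaplan-Meier cumulative-incidence curves by birth year
#'
#' Tidy per-age curves for a set of birth years (for export/plotting).
#'
#' @inheritParams cumulative_incidence
#' @param birth_years Birth years to include (default: all present).
#' @return `data.frame` with `birth_year`, `age`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
incidence_curves <- function(records, birth_years = NULL) {
  dt <- data.table::as.data.table(records)
  if (is.null(birth_years)) birth_years <- sort(unique(dt$birth_year))
  do.call(rbind, lapply(birth_years, function(y) {
    sub <- dt[dt$birth_year == y]
    fit <- survival::survfit(survival::Surv(exit_age, event) ~ 1, data = sub,
                             conf.type = "plain")
    data.frame(birth_year = y, age = fit$time, estimate = 1 - fit$surv,
               ci_low = pmax(0, 1 - fit$surv - 1.96 * fit$std.err * fit$surv),
               ci_high = pmin(1, 1 - fit$surv + 1.96 * fit$std.err * fit$surv))
  }))
}

#' Cox birth-cohort trend with mother-clustered robust errors
#'
#' Fits a proportional-hazards model on the attained-age time scale with
#' birth year as a categorical factor (reference `reference_year`), adjusted
#' for sex, using Efron tie handling and a cluster-robust sandwich variance
#' over families.  Years without any event are reported as missing with a
#' flag rather than as infinite coefficients.  With `age_window`, children
#' still at risk at the window start enter late and events beyond the window
#' end are censored there, emulating the age-specific trend analyses.
#'
#' @param records Survival records ([as_survival_records()]).
#' @param reference_year Reference birth cohort (HR = 1).
#' @param age_window Optional inclusive whole-year window, e.g. `c(7, 12)`.
#' @param continuous_year Also fit a log-linear trend in birth year and
#'   attach it as attribute `"continuous"`.
#' @return `data.frame` of class `trend_estimate`: `birth_year`, `hr`,
#'   `ci_low`, `ci_high`, `log_hr_se` (robust), `events`, `zero_events`.
#' @export
cox_birth_year_trend <- function(records, reference_year = 1982,
                                 age_window = NULL, continuous_year = FALSE) {
  dt <- data.table::as.data.table(records)
  stopifnot(length(unique(dt$birth_year)) >= 2L, sum(dt$event) > 0)
  if (!is.null(age_window)) {
    lo <- age_window[1]
    hi_excl <- age_window[2] + 1
    dt <- dt[dt$exit_age > lo]
    dt[, event := as.integer(event == 1L & exit_age < hi_excl)]
    dt[, entry_age := lo]
    dt[, exit_age := pmin(exit_age, hi_excl)]
  } else {
    dt[, entry_age := 0]
  }
  ev <- dt[, .(events = sum(event)), by = "birth_year"]
  zero_years <- ev$birth_year[ev$events == 0L & ev$birth_year != reference_year]
  fit_dt <- dt[!dt$birth_year %in% zero_years]
  fit_dt[, byf := stats::relevel(factor(birth_year),
                                 ref = as.character(reference_year))]
  fit <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ byf + sex,
    data = fit_dt, ties = "efron", cluster = family_id, x = FALSE, y = FALSE)
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))  # robust (sandwich) variance when cluster given
  is_year <- grepl("^byf", names(cf))
  yrs <- as.integer(sub("^byf", "", names(cf)[is_year]))
  out <- data.frame(
    birth_year = c(reference_year, yrs, zero_years),
    hr = c(1, exp(cf[is_year]), rep(NA_real_, length(zero_years))),
    ci_low = c(1, exp(cf[is_year] - 1.96 * se[is_year]),
               rep(NA_real_, length(zero_years))),
    ci_high = c(1, exp(cf[is_year] + 1.96 * se[is_year]),
                rep(NA_real_, length(zero_years))),
    log_hr_se = c(0, se[is_year], rep(NA_real_, length(zero_years))),
    row.names = NULL)
  out <- merge(out, ev, by = "birth_year", all.x = TRUE)
  out$zero_events <- out$birth_year %in% zero_years
  out <- out[order(out$birth_year), ]
  rownames(out) <- NULL
  class(out) <- c("trend_estimate", "data.frame")
  attr(out, "fit") <- fit
  if (continuous_year) {
    cfit <- survival::coxph(
      survival::Surv(entry_age, exit_age, event) ~ birth_year + sex,
      data = fit_dt, ties = "efron", cluster = family_id)
    attr(out, "continuous") <- c(
      log_hr_per_year = unname(stats::coef(cfit)["birth_year"]),
      se = sqrt(diag(cfit$var))[1])
  }
  out
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat("Birth-cohort hazard-ratio trend (robust, mother-clustered)\n")
  print.data.frame(utils::head(as.data.frame(x), 40), digits = 4)
  if (nrow(x) > 40) cat("...", nrow(x) - 40, "more years\n")
  invisible(x)
}
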