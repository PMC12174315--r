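## Environmental risk-factor associations.
##
## Two designs: the full-cohort Cox model (attained-age time scale, adjusted,
## mother-clustered robust errors) and the sibling comparison (the same model
## stratified by mother, which cancels every exposure shared by siblings and
## so separates direct associations from familial confounding).  Factors that
## are monotone within a sibship by construction (maternal age, birth order,
## education, serious life events) cannot be meaningfully sibling-compared
## and are flagged as ineligible.

#' Catalogue of environmental factors
#'
#' Registered factors, their coding, and whether the sibling comparison is
#' meaningful for them.
#'
#' @return `data.frame` with `factor`, `coding`, `sibling_appropriate`,
#'   `reason`.
#' @export
factor_catalogue <- function() {
  data.frame(
    factor = c("maternal_smoking", "maternal_bmi", "maternal_infection",
               "cesarean", "gestational_age", "birth_weight",
               "maternal_age", "birth_order", "maternal_education",
               "serious_life_event"),
    coding = c("binary", "continuous", "binary", "binary",
               "categorical", "categorical", "continuous", "continuous",
               "categorical", "binary"),
    sibling_appropriate = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                            FALSE, FALSE, FALSE, FALSE),
    reason = c("", "", "", "", "", "",
               "monotone within sibship", "monotone within sibship",
               "monotone (non-decreasing) within sibship",
               "monotone within sibship"),
    stringsAsFactors = FALSE)
}

#' Is the sibling comparison design meaningful for a factor?
#'
#' @param factor Factor name (must be in [factor_catalogue()]).
#' @return List with `sibling_appropriate` and `reason`.
#' @export
eligibility_check <- function(factor) {
  cat_ <- factor_catalogue()
  row <- cat_[cat_$factor == factor, ]
  if (nrow(row) == 0L) {
    stop("eligibility_check: unknown factor '", factor, "'", call. = FALSE)
  }
  list(sibling_appropriate = row$sibling_appropriate, reason = row$reason)
}

# default category bounds; extreme low birth weight (<1500 g) is its own
# class, reference categories are the modal ones
.default_cutpoints <- list(
  birth_weight = list(breaks = c(-Inf, 1500, 2500, 4000, Inf),
                      labels = c("<1500", "1500-2499", "2500-3999", ">=4000"),
                      ref = "2500-3999"),
  gestational_age = list(breaks = c(-Inf, 32, 37, 42, Inf),
                         labels = c("<32", "32-36", "37-41", ">=42"),
                         ref = "37-41"),
  maternal_education = list(ref = "3")
)

# build the model column(s) for a factor; returns a vector/factor
.code_factor <- function(records, factor, cutpoints = .default_cutpoints) {
  x <- records[[factor]]
  if (is.null(x)) {
    stop("factor '", factor, "' is not a column of the records",
         call. = FALSE)
  }
  cp <- cutpoints[[factor]]
  if (factor %in% c("birth_weight", "gestational_age")) {
    f <- cut(x, breaks = cp$breaks, labels = cp$labels, right = FALSE)
    stats::relevel(f, ref = cp$ref)
  } else if (factor == "maternal_education") {
    stats::relevel(factor(x), ref = cp$ref)
  } else {
    x
  }
}

.default_adjustment <- c("birth_year", "sex", "maternal_age",
                         "maternal_education", "maternal_bmi",
                         "maternal_smoking")

.assoc_rows <- function(fit, analysis, factor, n_used, n_strata = NA_integer_,
                        flag = "") {
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  keep <- grepl("^\\.factor", names(cf))
  data.frame(
    factor = factor,
    term = sub("^\\.factor", "", names(cf)[keep]),
    analysis = analysis,
    hr = exp(cf[keep]),
    ci_low = exp(cf[keep] - 1.96 * se[keep]),
    ci_high = exp(cf[keep] + 1.96 * se[keep]),
    log_hr_se = se[keep],
    n_used = n_used,
    n_informative_strata = n_strata,
    flag = flag,
    row.names = NULL)
}

#' Full-cohort Cox association of a factor with the outcome
#'
#' Attained-age time scale, adjusted for the default covariate set (birth
#' year, sex, maternal age, education, BMI and smoking, minus the factor
#' itself), Efron ties, and mother-clustered robust standard errors.
#' Children with missing factor values are dropped listwise and counted.
#'
#' @param records Survival records ([as_survival_records()]).
#' @param factor Name of the exposure column.
#' @param adjustment Covariate names to adjust for.
#' @return `data.frame` of class `association_estimate` (one row per
#'   non-reference level for categorical factors).
#' @export
cox_full_cohort <- function(records, factor,
                            adjustment = .default_adjustment) {
  dt <- data.table::as.data.table(records)
  adjustment <- setdiff(adjustment, factor)
  adjustment <- intersect(adjustment, names(dt))
  use <- stats::complete.cases(dt[, c(factor, adjustment, "exit_age",
                                      "event", "family_id"), with = FALSE])
  dt <- dt[use]
  dt[, .factor := .code_factor(dt, factor)]
  flag <- ""
  if (is.numeric(dt$.factor) && length(unique(dt$.factor)) == 2L) {
    ev <- dt$event == 1L
    if (length(unique(dt$.factor[ev])) < 2L) {
      flag <- "no exposure variation among cases"
    }
  }
  form <- stats::as.formula(paste(
    "survival::Surv(exit_age, event) ~ .factor +",
    paste(adjustment, collapse = " + ")))
  fit <- survival::coxph(form, data = dt, ties = "efron",
                         cluster = family_id)
  out <- .assoc_rows(fit, "full_cohort", factor, n_used = nrow(dt),
                     flag = flag)
  class(out) <- c("association_estimate", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Sibling-stratified Cox association (sibling comparison design)
#'
#' The same proportional-hazards model stratified by mother: only sibships
#' discordant in both exposure and outcome timing contribute information,
#' and every family-constant confounder cancels.  Errors if no informative
#' stratum exists.
#'
#' @inheritParams cox_full_cohort
#' @return `data.frame` of class `association_estimate` with
#'   `n_informative_strata` filled in.
#' @export
cox_sibling_stratified <- function(records, factor,
                                   adjustment = .default_adjustment) {
  elig <- eligibility_check(factor)
  if (!elig$sibling_appropriate) {
    stop("cox_sibling_stratified: sibling analysis is not meaningful for '",
         factor, "' (", elig$reason, ")", call. = FALSE)
  }
  dt <- data.table::as.data.table(records)
  adjustment <- setdiff(adjustment, c(factor, "birth_year"))
  adjustment <- intersect(adjustment, names(dt))
  use <- stats::complete.cases(dt[, c(factor, adjustment, "exit_age",
                                      "event", "family_id"), with = FALSE])
  dt <- dt[use]
  dt[, .factor := .code_factor(dt, factor)]
  fx <- as.numeric(as.integer(factor(dt$.factor)))
  info <- dt[, .(ok = (sum(event) >= 1L) & .N >= 2L &
                   (stats::var(fx[.I]) > 0)), by = "family_id"]
  n_info <- sum(info$ok)
  if (n_info == 0L) {
    stop("cox_sibling_stratified: no informative sibships for '", factor,
         "'", call. = FALSE)
  }
  rhs <- paste(c(".factor", adjustment, "strata(family_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("survival::Surv(exit_age, event) ~", rhs))
  fit <- survival::coxph(form, data = dt, ties = "efron")
  out <- .assoc_rows(fit, "sibling", factor, n_used = nrow(dt),
                     n_strata = n_info)
  class(out) <- c("association_estimate", "data.frame")
  attr(out, "fit") <- fit
  out
}
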