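## Counterfactual heritability attenuation.
##
## If a rise in cumulative incidence were driven entirely by new non-shared
## environmental liability variance, the genetic variance would stay fixed
## while total variance grows, so heritability must fall.  Two mechanisms are
## implemented:
##
## variance-inflation (default): keep the threshold t0 = Phi^-1(1 - p0) fixed
##   and inflate the total liability variance to V so that the upper-tail
##   probability at t0 / sqrt(V) equals p0 + delta; then h2' = h2 / V.
##
## exposure-shift: a fraction pi of the population acquires a liability mean
##   shift delta_mu solved to produce the incidence increase; the induced
##   between-group variance pi (1 - pi) delta_mu^2 joins the environmental
##   side, giving h2' = h2 / (1 + pi (1 - pi) delta_mu^2).

#' Expected heritability under an environment-driven incidence rise
#'
#' @param baseline_h2 Heritability before the rise (in (0, 1]).
#' @param baseline_prevalence Cumulative incidence before the rise.
#' @param delta_incidence Absolute incidence increase (e.g. `0.004` for 40
#'   cases per 10,000 children); `<= 0` returns the identity result.
#' @param mechanism `"variance_inflation"` (default) or `"exposure_shift"`.
#' @param exposed_fraction Fraction receiving the mean shift under the
#'   exposure-shift mechanism.
#' @return Object of class `attenuation_result`: `baseline_h2`,
#'   `baseline_prevalence`, `delta_incidence`, `new_total_variance`,
#'   `attenuated_h2`, `mechanism` (plus `mean_shift` for exposure-shift).
#' @examples
#' attenuated_h2(0.83, 0.005, 0.004)
#' @export
attenuated_h2 <- function(baseline_h2, baseline_prevalence, delta_incidence,
                          mechanism = c("variance_inflation",
                                        "exposure_shift"),
                          exposed_fraction = 0.2) {
  mechanism <- match.arg(mechanism)
  if (baseline_h2 <= 0 || baseline_h2 > 1) {
    stop("attenuated_h2: baseline_h2 must lie in (0, 1]", call. = FALSE)
  }
  if (baseline_prevalence <= 0 ||
      baseline_prevalence + max(delta_incidence, 0) >= 1) {
    stop("attenuated_h2: prevalences must lie in (0, 1)", call. = FALSE)
  }
  res <- list(baseline_h2 = baseline_h2,
              baseline_prevalence = baseline_prevalence,
              delta_incidence = delta_incidence,
              mechanism = mechanism)
  if (delta_incidence <= 0) {
    res$new_total_variance <- 1
    res$attenuated_h2 <- baseline_h2
    return(structure(res, class = "attenuation_result"))
  }
  t0 <- stats::qnorm(baseline_prevalence, lower.tail = FALSE)
  p1 <- baseline_prevalence + delta_incidence
  if (mechanism == "variance_inflation") {
    z1 <- stats::qnorm(p1, lower.tail = FALSE)
    V <- (t0 / z1)^2
    res$new_total_variance <- V
    res$attenuated_h2 <- baseline_h2 / V
  } else {
    pi_e <- exposed_fraction
    stopifnot(pi_e > 0, pi_e < 1)
    f <- function(d) {
      pi_e * stats::pnorm(t0 - d, lower.tail = FALSE) +
        (1 - pi_e) * baseline_prevalence - p1
    }
    d <- stats::uniroot(f, interval = c(0, 20), tol = 1e-12)$root
    V <- 1 + pi_e * (1 - pi_e) * d^2
    res$mean_shift <- d
    res$new_total_variance <- V
    res$attenuated_h2 <- baseline_h2 / V
  }
  structure(res, class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf(
    "Heritability attenuation (%s): %.3f -> %.3f\n", x$mechanism,
    x$baseline_h2, x$attenuated_h2))
  cat(sprintf(
    "  incidence %.4f -> %.4f; new total liability variance %.4f\n",
    x$baseline_prevalence, x$baseline_prevalence + max(0, x$delta_incidence),
    x$new_total_variance))
  invisible(x)
}
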