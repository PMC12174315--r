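# aetrend

Incidence trends and moderated AE liability-threshold heritability in
sibling cohorts.

## The problem

The incidence of childhood-onset type 1 diabetes (T1D) roughly doubled in
many countries between the early 1980s and 2000 and then plateaued.  If
environmental change drove the rise, the share of disease-liability
variance explained by environmental factors should have grown — i.e.
heritability should have fallen across birth cohorts.  Nationwide registry
studies test this by linking millions of children to their full siblings
and fitting liability-threshold variance-component models by birth year.
Individual-level registry data cannot be shared, so `aetrend` provides the
entire analysis chain together with a calibrated synthetic registry
generator, letting the methods be developed, validated and taught on data
with known generating truths.

The package is for biostatisticians and genetic epidemiologists working
with family-based registry designs: every estimator is exercised against
configurations where the true answer is known by construction.

## The model

A child's latent liability is

    L = a(y) A + e(y) E + gamma_sex * sex + covariate shifts

with `A` additive-genetic (correlation 1/2 between full siblings), `E`
non-shared environment, and birth-year-moderated paths

    a(y) = a0 + beta_a (y - 1996),   e(y) = e0 + beta_e (y - 1996),

standardised so `a0^2 + e0^2 = 1` at the median birth year.  Disease occurs
when `L` crosses a threshold; heritability by cohort is
`h2(y) = a(y)^2 / (a(y)^2 + e(y)^2)`.  Sibling pairs are aggregated into
outcome cells whose probabilities are bivariate-normal orthant
probabilities (Genz's algorithm, implemented in `bvn_orthant()`), and the
model is fitted by maximum likelihood with family-bootstrap confidence
intervals.  Around the core model sit: Kaplan–Meier / Cox birth-cohort
incidence trends with mother-clustered robust errors, full-cohort and
sibling-stratified risk-factor Cox models, a counterfactual
heritability-attenuation calculation, and a survival-setting causal
mediation decomposition (natural direct/indirect effects by g-computation).

## A worked example

```r
library(aetrend)

cfg    <- generator_config(n_families = 150000, seed = 7)
cohort <- simulate_cohort(cfg)          # 260,243 children, 0.678% cases
cells  <- make_sibling_pairs(cohort)
cells
#> Sibling-pair outcome cells: 2037 cells, 143,856 pairs (72 concordant-affected, 1,821 discordant)

fit <- fit_ae(cells, model = "model4")
fit
#> AE liability-threshold fit (model4)
#>   pairs: 143,856; logLik = -11630.653; AIC = 23269.306; free params = 4
#>   h2(ref) = 0.8063; e2(ref) = 0.1937

attenuated_h2(0.83, 0.005, 0.004)
#> Heritability attenuation (variance_inflation): 0.830 -> 0.700
#>   incidence 0.0050 -> 0.0090; new total liability variance 1.1856
```

The generating heritability here is 0.83; at 144k pairs (72 of them
concordant-affected) the estimate is 0.81 with considerable noise, and at
the two-million-pair scale the validation suite runs, it concentrates
within a few hundredths of the truth.  The attenuation result reads: if a
40-per-10,000 incidence rise were purely environmental, total liability
variance would grow ~19% and heritability would fall to 0.70.

An end-to-end run (generate → incidence → heritability → attenuation →
risk factors → mediation) is one call:

```r
run_pipeline(cfg, out_dir = "out", seed = 1)
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --config cfg.yaml
--out out/`.  Outputs are tidy CSVs (`incidence_trend.csv`,
`heritability_curve.csv`, `risk_factors.csv`, `mediation.csv`, ...) plus a
seed/digest manifest for reproducibility.

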