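# weibcohort

Parametric survival analysis for very small right-censored cohorts, built
around a 16-patient mixed-phenotype acute leukemia (MPAL) registry cohort
treated with the CLAG-M regimen — eight patients in first-line induction
(Group A) and eight in salvage (Group B).

With only a handful of deaths per group, a Kaplan-Meier staircase cannot say
whether the death rate is rising or falling. `weibcohort` answers that with
the two-parameter Weibull model

    S(t) = exp(-(t/η)^β),    h(t) = (β/η) (t/η)^(β-1),    β, η > 0,

whose shape β classifies the hazard regime: β < 1 decreasing ("infant
mortality"), β = 1 constant (exponential), β > 1 increasing ("aging"). The
package provides, for any cohort table of `(os_months, event)` records:

- **Cohort handling** — packaged fixture (`clagm_cohort()`), CSV reader with
  column mapping (`read_cohort_csv()`), response tabulation with overall
  response rate (`tabulate_response()`).
- **Nonparametrics** — product-limit estimate (`km_estimate()`), KM and plain
  sample medians (`km_median()`, `sample_median()`).
- **Weibull MLE under right censoring** (`weibull_mle()`): profile-based
  optimisation (time-unit-invariant shape), delta-method standard errors,
  90% log-scale Wald intervals (`wald_ci_log()`), AIC, hazard classification
  (`classify_hazard()`), and median-rank probability-plot coordinates with
  exact beta order-statistic bounds (`weibull_plot_points()`).
- **Bayesian shape inference** via the profile likelihood: deterministic
  quadrature (`posterior_quadrature()`) and a seeded random-walk Metropolis
  sampler (`posterior_mcmc()`), with priors (`flat_prior()`, `gamma_prior()`,
  `lognormal_prior()`) recorded in every summary.
- **Posterior comparison** — kernel-density overlapping index
  (`overlap_index()`), reporting OI and 1 − OI.
- **Simulation** — right-censored Weibull cohort generator
  (`simulate_cohort()`) and a parameter-recovery harness
  (`recovery_experiment()`).
- **Orchestration** — `run_pipeline()` writes a reproducible report bundle
  with a manifest; `cohort_cli()` (wrapper script in `inst/cli/`) exposes
  `report`, `fit`, `km`, `bayes`, `overlap`, `simulate` subcommands.

Fitted objects are tibble-friendly: `tidy()`, `glance()` and `autoplot()`
methods are provided throughout.

## Worked example

```r
library(weibcohort)

fit <- weibull_mle(clagm_cohort("A"))
fit
#> Right-censored Weibull fit (A): N = 8, events = 4, censored = 4
#>   shape    0.6999  [90% CI 0.3899, 1.2563]  se 0.2489  (decreasing hazard)
#>   scale   47.5435  [90% CI 14.4378, 156.5594]  se 34.4480
#>   total time at risk = 187, log-likelihood = -18.7505, AIC = 41.50090
```

The shape estimate 0.70 (< 1) says the death rate in the first-line group is
*decreasing* over time — early deaths dominate — but its 90% interval
(0.39, 1.26) straddles 1: eight patients cannot rule out a constant hazard.
The scale, 47.5 months, is the time by which about 63% of patients would have
died under the fitted model. The Bayesian route tells the same story with
small-sample-honest intervals:

```r
posterior_mcmc(clagm_cohort("A"), seed = 42)
#> Weibull shape posterior (mcmc; prior flat(0, 10])
#>   median = 0.7394, 90% CrI = [0.3732, 1.2018]
#>   45000 retained samples (seed 42), acceptance 0.73, ESS 4430

glance(km_estimate(clagm_cohort("A")))
#> # A tibble: 1 × 5
#>       n events censored median label
#>   <int>  <int>    <int>  <dbl> <chr>
#> 1     8      4        4      9 A
```

The KM median overall survival in Group A is 9 months. Comparing the two
groups' shape posteriors with the overlapping index:

```r
pa <- posterior_mcmc(clagm_cohort("A"), seed = 42)
pb <- posterior_mcmc(clagm_cohort("B"), seed = 43)
overlap_index(pa$samples, pb$samples)
#> Overlapping index = 0.1296 (1 - OI = 0.8704)
#>   KDE bandwidths 0.02664 / 0.07651, grid [-0.142, 6.75] x 2048, n = 45000 / 45000
```

A small OI: the two groups' shape posteriors barely overlap (Group B's fitted
shape is 1.91, an increasing hazard). The full bundle — response tables, KM
curves, fit reports, plot coordinates, posteriors, overlap, manifest:

```r
run_pipeline("ALL", output_dir = "bundle", seed = 1)
```

or from a shell:

```sh
Rscript inst/cli/weibcohort.R report --input ALL --out bundle --seed 1
```

See the vignette (`vignettes/weibull-small-cohorts.Rmd`) for the model,
the profile-likelihood posterior, numerical choices, and known limitations —
including why the salvage-group shape reported for the original
day-resolution data is not recoverable from the published month-resolution
records.

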