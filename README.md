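# agearch

Age-dependent trait architecture under the exposure-accumulation
liability-threshold model.

## What this package is for

Heritability of many complex traits and disease liabilities decreases
with age, and polygenic risk scores (PRS) predict disease less well in
older patients. `agearch` is a simulation and estimation toolkit for
researchers in statistical genetics and genetic epidemiology who want to
separate the candidate explanations and quantify their effect on
prediction:

- **Exposure accumulation (EA).** Liability gains independent
  environmental increments each age bin,

  L = G + E + age + &Sigma;<sub>a&le;age</sub> E<sub>a</sub>,

  so environmental variance — and total variance — grows with age while
  genetic variance is constant, driving h² = var(G)/var(L) down.
- **The liability-threshold mechanism.** Under a threshold model, cases
  whose liability crosses the threshold late in life sit closer to the
  healthy population, so *any* predictor correlated with liability —
  genetic or not — separates old-onset cases from controls less well.
- **Incident vs prevalent designs.** Predicting new diagnoses within an
  age window (incident) loses accuracy with age faster than associating
  with accumulated diagnoses (prevalent); on the liability scale,
  prevalent R² is flat while incident R² declines.

The package provides liability-threshold disease simulators with and
without EA, Haseman–Elston heritability and cross-age-bin genetic
correlation estimators with block-jackknife standard errors, a denoised
three-visit longitudinal phenotypic correlation
&rho;(v1,v3)/&rho;(v1,v2) that cancels measurement-error attenuation,
calibrated predictors and QRS (quantitative risk score) construction,
incident/prevalent case-control sets with 1:1 down-sampling,
observed-to-liability-scale R² conversion (Lee et al. 2012, eq. 14),
weighted age-trend fits with likelihood-ratio tests and Monte-Carlo
standard errors, and the attribution statistics

&tau; = &Sigma;<sub>d</sub> max(&Delta;R²<sub>QRS,d</sub>, &Delta;R²<sub>PRS,d</sub>) / &Sigma;<sub>d</sub> &Delta;R²<sub>PRS,d</sub>,&emsp;
expected combined change = 1 − (1 + &Delta;R²<sub>QRS</sub>)(1 + &Delta;h²).

A synthetic-cohort generator supplies genotypes (PLINK .bed/.bim/.fam),
longitudinal trait visits, diagnosis ages, censoring and medication
flags with the statistical structure the analysis assumes, so the whole
pipeline runs at desk scale. See `vignettes/agearch-methods.Rmd` for the
models, assumptions and numerical choices.

## Worked example

Simulate the EA liability-threshold model at the study conditions
(100,000 individuals, h² = 0.3, five onset bins of 2%, per-bin increment
variance 0.05), then measure how a predictor with 20% liability-scale R²
loses incident-prediction accuracy with onset age:

```r
library(agearch)

ea <- simulate_ea_threshold(100000, h2 = 0.3, increment_var = 0.05, seed = 1)
ea
#> <simulated_disease> model=ea, n=100000, h2=0.30, 5 bins x 2.0%
#>   cases per bin: 2000, 2000, 2000, 2000, 2000

var(ea$liability$G) / var(ea$liability$L_bin5)
#> [1] 0.250        # h2 diluted from 0.30 by ~20% accumulated variance

prs <- calibrate_predictor(ea$liability$G + ea$liability$E0, 0.2, seed = 2)
r2 <- sapply(1:5, function(k) {
  cc <- sim_case_control_sets(ea, "incident", k, seed = k)
  idx <- c(cc$cases, cc$controls)
  observed_r2(prs[idx], as.integer(idx %in% cc$cases))$value
})
round(r2, 3)
#> [1] 0.255 0.159 0.128 0.112 0.075   # observed R2 by onset-age bin

tr <- fit_metric_trend(metric_series(r2, rep(0.01, 5), c(44, 52, 60, 68, 76),
                                     metric = "r2_obs"), seed = 3)
tr
#> <trend_estimate> slope = -0.00511/yr (MC se 0.00040), LRT p = 3.51e-38
```

The observed-scale R² falls from 0.255 in the youngest onset quintile to
0.075 in the oldest: the liability-threshold mechanism plus accumulating
environmental variance erode the predictor even though the genetic
effects are fixed. The denoised longitudinal correlation recovers the
underlying liability decay despite 50% measurement-error variance:

```r
v <- simulate_longitudinal_liability(5000, "stationary_decay", beta = 0.02,
                                     visit_ages = c(50, 55, 60),
                                     measurement_error_var = 0.5, seed = 4)
denoised_phenotypic_correlation(v, seed = 5)
#> <correlation_estimate> kind=denoised: rho_10yr = 0.8177 (se 0.0307), n = 5000
```

0.8177 against the true exp(−10 × 0.02) = 0.8187: the ratio of
correlations cancels the attenuation a raw visit-to-visit correlation
would suffer.

The full chain — simulate, estimate per-bin h², denoise, build PRS/QRS,
fit trends, attribute — runs from one configuration:

```r
report <- run_pipeline(default_run_config(seed = 1), output_dir = "demo_run")
```

which writes the interchange tables (subjects, visits, diagnoses,
estimates, correlations, trends, attribution) plus PLINK genotypes and a
summary under `demo_run/`. A thin CLI over the same functions is in
`inst/scripts/agearch-cli.R`.

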