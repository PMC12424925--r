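---
title: "Age-dependent trait architecture under exposure accumulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-dependent trait architecture under exposure accumulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agearch)
```

## The scientific problem

Heritability of many quantitative traits and disease liabilities falls with
age. Two mechanisms can produce this. Under *gene-age interaction*
(including proportional amplification, where genetic and environmental
variance scale together and heritability is unchanged), the genetic effects
themselves depend on age. Under *exposure accumulation* (EA), genetic
variance is constant while independent environmental insults accrue over
life, so total variance grows and the genetic fraction shrinks. The two
mechanisms have different consequences for risk prediction: under EA, a
polygenic score loses accuracy in older patients even though the biology it
captures is unchanged.

`agearch` implements, at desk scale, the full chain of analyses needed to
distinguish these mechanisms and to quantify their effect on prediction
accuracy:

1. liability-threshold disease simulators with and without EA;
2. per-age-bin heritability and cross-bin genetic correlation via
   Haseman-Elston (HE) regression;
3. a denoised longitudinal phenotypic correlation that cancels
   measurement-error attenuation;
4. incident and prevalent case-control designs, calibrated predictors,
   observed- and liability-scale accuracy metrics, and the quantitative
   risk score (QRS) construction;
5. weighted linear age-trend fits with likelihood-ratio tests and
   Monte-Carlo standard errors, variance decomposition, and the
   attribution statistics (the explained proportion tau and the combined
   EA + liability-threshold expected change).

## The liability-threshold simulators

Each individual has liability $L = G + E$ with
$G \sim N(0, h^2)$ and $E \sim N(0, 1 - h^2)$. Onset age is modelled by
ranking: in each of $k = 1, \dots, 5$ age bins, the top 2% of the
not-yet-diseased by current liability become cases, so bin 1 holds the
youngest-onset (highest-liability) cases. Ranking rather than a fixed
numeric threshold makes the construction invariant to proportional
amplification of the liability scale: multiplying $G$ and $E$ by a common
age-dependent factor permutes nobody.

In EA mode, every individual receives an independent
$N(0, \sigma^2_{EA})$ increment when the population moves to each older
bin, added cumulatively *before* that bin's cases are extracted. With
$\sigma^2_{EA} = 0.05$ over five bins, the cumulative increments present
in bin 5 (four of them) carry $4 \times 0.05 = 0.2$, i.e. about 20% of
the initial liability variance, and the genetic fraction of bin-5
liability is diluted from 0.3 to $0.3 / 1.2 = 0.25$. Setting
$\sigma^2_{EA} = 0$ reproduces the linear simulator exactly, draw for
draw.

Case-control sets are built two ways. *Prevalent association* at bin $k$
takes everyone with onset at or before $k$ as cases and the not-yet-
diseased as controls. *Incident prediction* takes onset exactly at $k$ as
cases and the never-diseased-by-end-of-bin as controls. Controls are
down-sampled uniformly to a 1:1 ratio so odds ratios, hazard ratios and
observed-scale $R^2$ are comparable across bins. Two textual ambiguities
were resolved as follows: incident controls exclude the incident cases
themselves (the natural reading of "all individuals below the
threshold"), and EA increments are applied on entering a bin, before case
extraction.

```{r simulators}
lin <- simulate_linear_threshold(100000, h2 = 0.3, seed = 1)
ea <- simulate_ea_threshold(100000, h2 = 0.3, increment_var = 0.05, seed = 1)
var(ea$liability$G) / var(ea$liability$L_bin5)  # ~0.25 by dilution
```

## Haseman-Elston estimation per age bin

Mixed-model REML and LD-score regression are the field's estimators at
biobank scale; their estimands (per-bin $h^2$, cross-bin $r_g$) are
reproduced here with Haseman-Elston moment estimators, which are
tractable at $n \approx 5000$ on one CPU. Within a
bin, the phenotype is residualized on sex and within-bin age,
standardized, and the pairwise products $y_i y_j$ are regressed with
intercept on the off-diagonal entries of the genetic relationship matrix;
the slope estimates $h^2$. Across two bins — disjoint samples, so there
is no sample-overlap term, the same property the summary-statistic
approach relies on — the cross products $y_{a,i} y_{b,j}$ regressed on
the cross-sample relatedness estimate the genetic covariance, normalized
by $\sqrt{\hat h^2_a \hat h^2_b}$. Standard errors come from a
delete-one-block jackknife over individuals (100 contiguous blocks by
default), implemented with row-aggregate subtraction so each
leave-block-out slope costs $O(n)$ rather than $O(n^2)$.

Estimates are deliberately never truncated to $[0, 1]$ or $[-1, 1]$:
truncation would bias the downstream trend fits, and unbiasedness matters
more than plausibility for a quantity that is subsequently averaged. The
cross-bin estimator requires both bins to be genotyped on the same SNP
panel (as age bins of one cohort are); pooled standardization across two
panels with different allele frequencies attenuates the covariance. The
estimator has no analogue of a constrained regression intercept; this is
a substitution difference from the summary-statistic approach, noted
rather than patched. The pipeline also accepts externally computed
per-bin estimate tables (value + standard error), so biobank-scale REML
or LD-score output can be dropped in unchanged.

## Scaling correlations and the denoised longitudinal estimator

Correlations between bins with different age gaps are compared on a
common 10-year gap under the working model
$\rho(\Delta) = e^{-\beta\Delta}$:
$\rho_{10} = \exp(10 \ln \rho / \Delta)$. Neighboring-bin estimates
(pairs 1-2, 2-3, 3-4, 4-5; the 10 pairwise correlations carry only four
degrees of freedom) are pooled by inverse-variance weighting, and the
deficit from 1 is tested one-sided via $z = (1 - \hat\rho)/se$ (the
two-sided p is reported alongside).

Observed phenotypic correlations are attenuated by measurement error. For
individuals with three visits, the ratio
$\rho(v_1, v_3) / \rho(v_1, v_2)$ cancels the attenuation factor of
visit 1 exactly; under constant liability variance the visit-2 and
visit-3 factors cancel as well, leaving the liability correlation over
the $t_3 - t_2$ gap. The per-year decay is $\ln(\text{ratio})$ divided by
the cohort-average $t_3 - t_2$ (per-individual spacing is not used), and
the result is reported on the 10-year scale with a bootstrap-over-
individuals standard error (B = 200 by default). Two latent processes are
offered by the generator: a Wiener process (variance grows linearly, the
motivation for the exponential scaling) and a stationary
exponential-decay process (constant variance). The ratio cancellation is
exact only under constant variance, so the stationary process is the one
used for exact-recovery tests; under the Wiener process the cancellation
is approximate, which is a known property of the estimator rather than a
defect. Pearson correlation is used throughout, matching the linear
liability framework. Estimates with non-positive raw correlation cannot
be log-scaled and are excluded with a warning rather than imputed.

```{r denoise}
v <- simulate_longitudinal_liability(5000, "stationary_decay", beta = 0.02,
                                     visit_ages = c(50, 55, 60),
                                     measurement_error_var = 0.5, seed = 2)
denoised_phenotypic_correlation(v, seed = 3)  # recovers exp(-0.2) ~ 0.819
```

## Predictors and accuracy metrics

`calibrate_predictor()` adds Gaussian noise of variance
$\mathrm{var}(L)(1 - t)/t$ to a liability and standardizes, realizing a
target liability-scale $R^2$ of $t$; the study tiers are
$t \in \{0.99, 0.5, 0.2, 0.05\}$, spanning a near-perfect predictor down
to a typical polygenic score. In synthetic mode the PRS stand-in is
calibrated against the genetic component $G$ (not $L$), since a
polygenic score captures genetic signal only. Principal components are
not simulated (no population structure is generated); the covariate slots
accept them when supplied.

Observed-scale $R^2$ residualizes the 0/1 outcome on the design's
covariates (sex and principal components for genetic scores; sex and age
for the QRS) and squares the Pearson correlation with the score. The
conversion to liability-scale $R^2$ uses the ascertainment-corrected
transformation of Lee et al. (2012, eq. 14) with threshold
$t = \Phi^{-1}(1 - K)$ and mean case liability $z/K$. AUC is computed as
the Mann-Whitney concordance without covariate adjustment (the regression
metrics are adjusted; no adjusted-AUC variant is defined). Logistic,
linear and Cox coefficients are reported per standard deviation of the
score, with model-based standard errors; complete separation is flagged
as non-converged rather than reported as a finite effect.

The estimated disease liability is an L1-regularized *linear* (not
logistic) regression of case status on the quantitative traits —
consistent with a liability-threshold reading of the binary outcome —
with 10-fold cross-validation, no age covariate, and out-of-fold
predictions used as the score. The penalty uses the `2se` rule by
default: the largest penalty whose CV error is within two CV standard
errors of the minimum, the direct analogue of the standard one-standard-
error rule, chosen for stronger regularization. The QRS pipeline then
(1) rank-normalizes the estimated liability (Blom offset $c = 3/8$;
ties get average ranks), (2) residualizes QRS on age and sex and PRS on
sex plus any principal components (standardization precedes
residualization), (3) computes whole-population liability-scale $R^2$
for both, (4) adds Gaussian noise to the QRS until its liability-scale
$R^2$ matches the PRS's (the noise variance is solved analytically by
inverting the Lee transformation), (5) computes per-bin incident
observed $R^2$ on the shared case-control sets, and (6) repeats the
noise draw and control down-sampling 50 times, reporting Monte-Carlo
means and standard deviations. If the QRS is already weaker than the
PRS, no noise is added and a warning is raised.

Interval censoring for real (or simulated-cohort) diagnoses: cases are
split into quintiles of first-diagnosis age; per interval, cases are
those diagnosed inside it, controls those undiagnosed by its end who were
followed to the end *or lost to follow-up within it*. The
lost-to-follow-up clause is implemented as stated, with
`include_ltfu = FALSE` available to require full follow-up. Prevalent
association uses the five median case ages of the incident intervals as
baseline age points.

## Age trends, variance decomposition, attribution

A metric series (one estimate and standard error per bin, at the bin's
median age — median baseline age for heritability series, median onset
age for prediction-accuracy series) is fitted by maximum likelihood as
$v_k \sim N(a \cdot \text{age}_k + b, se_k)$, i.e. weighted least squares
with known noise. The null $a = 0$ is tested by likelihood ratio against
$\chi^2(1)$; validity rests on the bins being non-overlapping samples.
The slope's standard error is Monte-Carlo: each bin value is redrawn from
$N(\text{point}, se)$ and the fit repeated (1000 draws by default; the
description of the Gaussian's spread is read as a standard deviation
equal to the standard error, the conventional meaning). Changes are
reported as relative 10-year changes, $10a$ divided by the
whole-population estimate.

Variance decomposition per bin: $\mathrm{var}(G) = h^2 \cdot
\mathrm{var}(P)$ and $\mathrm{var}(E) = (1 - h^2)\mathrm{var}(P)$, by sex
when requested. EA moves points above the $\Delta\mathrm{var}(E) =
\Delta\mathrm{var}(G)$ diagonal ($E$ grows, $G$ flat); proportional
amplification moves them along it.

Attribution across diseases uses signed relative 10-year changes
(negative = decline), matching the axes on which the quantities are
compared:

$$\tau = \frac{\sum_d \max(\Delta R^2_{QRS,d},\; \Delta R^2_{PRS,d})}
             {\sum_d \Delta R^2_{PRS,d}},$$

where the elementwise max caps each disease's contribution at 100%
explained. The combined EA + liability-threshold expectation is
$1 - (1 + \Delta R^2_{QRS})(1 + \Delta h^2)$, positive for a decline;
its standard error treats the two inputs as independent (they derive
from near-disjoint information). Slope differences between predictors
use $z = (x - y)/\sqrt{se_x^2 + se_y^2}$.

## The synthetic cohort: what it emulates and what it does not

The generator draws baseline ages uniformly on [40, 79] (the age
distribution within quantile bins is not otherwise specified; uniform is
the neutral choice), sex as Bernoulli(0.5), and unlinked Hardy-Weinberg
genotypes with allele frequencies uniform on a configurable interval —
independence is the desk-scale idealization of a pruned moderate-LD
panel. Trait liabilities are $Zb + E$ with per-SNP effects
$N(0, h^2/m)$ on standardized dosages; a trait with per-bin EA variance
$\sigma^2_{EA}$ gives an individual in baseline-age bin $k$ exactly $k$
independent increments, so per-bin heritability follows
$h^2 / (1 + k\sigma^2_{EA})$. Visits repeat the liability plus fresh
measurement noise. Disease onset runs the same ranking machinery as the
dedicated simulators, with total prevalence split evenly over bins;
onset bins map to diagnosis ages uniform within 8-year windows of
[40, 80), and diagnoses after the censoring age (baseline + follow-up,
capped at 85) are unobserved. A disease may mix a named trait's genetic
and environmental components into its own liability (`link_trait`),
making that trait an informative QRS ingredient, as quantitative risk
factors are for real diseases. Medication flags are set with higher
probability among the diagnosed, and correction rules shift flagged
values additively — in trait units or in whole-population standard
deviations — keeping both corrected and uncorrected columns.

What passing tests on these data do **not** show about real cohorts:
there is no linkage disequilibrium or population structure, no
ascertainment into the cohort (the recruitment-bias resampler exists to
*test* such effects, not to create them), no competing mortality,
missingness, or diagnostic miscoding, and environmental increments are
exactly independent and Gaussian. Results on synthetic data validate the
estimators' internal consistency, not the biology.

## Numerical choices and degenerate inputs

* Liability ties in the ranking simulators are broken by a seeded random
  permutation (a measure-zero event for continuous liabilities, guarded
  anyway). Per-bin case counts use $\lfloor f n \rfloor$, remainder
  dropped.
* Monomorphic SNPs are excluded from standardization with a warning;
  constant phenotypes or residuals, all-equal rank-normal inputs,
  near-zero $\rho(v_1, v_2)$ in the denoising ratio, zero trend
  denominators and single-visit denoising requests all raise informative
  errors rather than returning numbers.
* Age-matched resampling discretizes age into 2-year histogram bins and
  draws identical per-bin quotas from both groups, proportional to the
  bin-wise minimum of the two densities — the largest target for which
  1:1 matching is feasible; disjoint supports are an error.
* All generators and estimators take explicit seeds and restore the
  caller's RNG state; the pipeline derives a logged child seed per stage
  from the master seed.
* Block jackknife uses contiguous index blocks; with fewer individuals
  than blocks, blocks shrink to single individuals.

## Problem sizes

The shipped tests exercise the estimators at the sizes the methods are
designed for at desk scale: liability simulators at $n = 100{,}000$;
HE heritability and cross-bin genetic correlation at $n = 5000$ with
2000 SNPs (single-replicate recovery) and $n = 500$ with 300 SNPs
(50-replicate unbiasedness); denoising coverage on grids of
$\beta \in \{0, 0.01, 0.02, 0.05\}$ with 1200-2000 individuals per
replicate; the end-to-end pipeline demo at $n = 5000$ (default) and
$n = 1200$ (tests). These sizes were chosen so that each property is
measured with enough precision to be meaningful while a full suite run
stays in the minutes range.

## Known limitations

* The HE substitution carries larger standard errors than REML at equal
  $n$; cross-bin correlations at desk-scale $n$ have standard errors of
  roughly 0.08, so only large deficits from 1 are detectable.
* The Lee et al. transformation is a normal-theory approximation; its
  round-trip error at $R^2_{liab} = 0.05$, $K = 0.1$, $P = 0.5$ is below
  0.01 but not zero.
* The denoising ratio assumes three visits and stationary liability
  variance for exact cancellation; more visits are not supported.
* No gene-age interaction generator (genetic correlation below 1 across
  bins) is included; the EA-vs-interaction contrast is tested from the
  estimator side only.
* Quantitative-trait measurements postdate diagnosis for prevalent cases
  in real cohorts; the QRS design inherits that caveat where it applies.
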