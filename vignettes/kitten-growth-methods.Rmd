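---
title: "Growth standards, neutering and body composition in kittens: models and methods"
author: "kittengrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth standards, neutering and body composition in kittens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kittengrowth)
```

# What the package does

`kittengrowth` implements two linked analyses of kitten growth:

1. **Clinic growth trajectories.** Longitudinal bodyweights of client-owned
   domestic shorthair kittens are cleaned through a multi-stage cascade,
   split into neuter-age cohorts, modelled with the Box-Cox Cole-Green
   (BCCG) distributional regression used for growth references, and
   compared with sex-specific growth standards on the z-score scale. A
   within-individual linear model then estimates the change in z-score
   from the last pre-neutering visit to the last available visit, per sex
   and neuter-age group, with single-step (Tukey-type) familywise
   adjustment.
2. **Littermate trial morphometrics.** Eleven body-composition and
   zoometric measures from neutered-vs-intact female littermate pairs are
   analysed jointly in a Bayesian multivariate mixed model with litter-
   and cat-level random effects correlated across measures, missing
   values imputed during fitting, fold-change-ratio contrasts against the
   pre-neutering baseline week, and simultaneous (sup-t) credible
   intervals.

Because the motivating clinic and colony datasets are proprietary, the
package ships first-class synthetic-data generators with fully known
ground truth; every downstream property is validated against that truth.

# The BCCG distribution and z-scores

A growth reference is three smooth curves of age: the median $M(t)$ (kg),
the coefficient of variation $S(t)$, and the Box-Cox power $L(t)$. At a
given age, a weight $y$ maps to

$$ z = \frac{(y/\mu)^{\nu} - 1}{\nu\,\sigma} \quad (\nu \neq 0), \qquad
   z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0), $$

with $(\mu, \sigma, \nu) = (M, S, L)$ at that age. The inverse map gives
centiles, $y_p = \mu(1 + \nu\sigma z_p)^{1/\nu}$ with $z_p = \Phi^{-1}(p)$.
Numerically, `expm1`/`log1p` forms keep both maps accurate down to
$|\nu| \approx 10^{-300}$, so the $\nu = 0$ branch is reached continuously.
The density (`bccgLogPdf`) includes the positive-support truncation
normalizer $\Phi(1/(\sigma|\nu|))$ of the Cole-Green construction, so it
integrates to one for every admissible parameter set; at $\nu = 0$ it is
exactly the lognormal density.

On the z-score scale a cohort that follows the standard is a horizontal
line at zero and the standard centiles are equally spaced horizontal
gridlines, which is what makes post-neutering "upward inclination"
directly readable from the trajectory plots.

# Fitting smooth L/M/S curves

`fitGrowthModel()` fits $\log\mu(x)$, $\log\sigma(x)$ and $\nu(x)$ against
transformed age $x = t^{0.1}$ (the transform that linearizes early, rapid
feline growth) by penalized maximum likelihood:

* cubic B-spline bases (8 interior knots, shared across curves) with
  difference penalties (P-splines): second order for the median and
  variation curves, first order for the power curve;
* cyclic Fisher-scoring backfitting in the Rigby-Stasinopoulos style:
  each cycle updates one curve by a penalized weighted least-squares step
  using the classical LMS expected-information weights
  ($w_\mu = 1/\sigma^2 + 2\nu^2$, $w_\sigma = 2$,
  $w_\nu = 7\sigma^2/4$), with step halving whenever the penalized
  deviance fails to decrease;
* per-cycle penalty weights re-solved so each curve holds a target
  effective df. Defaults are **8 / 4 / 1** for $\mu$ / $\sigma$ / $\nu$.
  We chose 8 for the median after simulating from a Gompertz-shaped truth:
  6 df visibly underfits the bend of the growth curve on the $t^{0.1}$
  scale and biases cohort trajectories by up to $-0.13$ z mid-growth,
  while 10-12 df buys no accuracy and raises variance where clinic visits
  are sparse. The Box-Cox power defaults to a *constant* (df 1, under a
  first-order difference penalty that shrinks the curve toward a
  constant): its per-observation Fisher information, $7\sigma^2/4$, is
  two orders of magnitude below the median's, so at clinic noise scales
  even a linear $\nu(x)$ is dominated by edge variance on the
  data-sparse young end of the $t^{0.1}$ scale. Raise `df["nu"]` when
  the data support an age-varying power;
* convergence on a relative penalized-deviance change below $10^{-6}$;
  the optimizer is deterministic, so refits on identical data are
  bit-identical.

Numerical guards: $\sigma$ is floored at $10^{-3}$ (noise-free inputs
would otherwise drive the likelihood to a boundary), $\nu$ coefficients
are clamped to $[-10, 10]$, and the penalty-weight search is run on a
penalty rescaled to the magnitude of the weighted Gram matrix so it is
invariant to the weights' scale. Between grid nodes, L/M/S are
interpolated with monotonicity-preserving (Fritsch-Carlson) cubic
Hermite splines in $x$, which keeps interpolated centiles non-crossing.

# The cleaning cascade

Each stage is a pure filter returning the surviving rows plus a one-row
report; removed row ids are carried so consecutive reports reconcile
exactly (`rows_in` of stage $k{+}1$ equals `rows_out` of stage $k$).

* **Eligibility.** Only preventative or healthy-diagnosis visits; no
  rolled-over or in-carrier weighings; drop cats with a sex/procedure
  conflict, an exclusion diagnosis before 208 weeks, no "normal" body
  condition rating at 78-130 weeks, any abnormal rating up to 208 weeks,
  or no remaining weight in the 5-91-week window.
* **BCS carry-over.** An unknown body-condition score inherits the score
  of the nearest-in-time visit whose weight is within 5%; ties go to the
  earlier visit, then file order.
* **Pound rounding.** A weight whose pound equivalent
  (1 kg = 2.2046226218 lb) is within $\varepsilon = 0.005$ lb of an
  integer is removed. On continuous weights this window coincidentally
  hits about 1% of honest rows; that false-positive rate is intrinsic to
  any tolerance-based detector and is measured in the tests.
* **Extreme outliers.** Weights above 3 times the median of all visits of
  cats older than 9 months (9 months $= 365.25/12 \times 9 / 7 = 39.13$
  weeks, the single declared convention) are removed at any age.
* **Population outliers.** Rows are split into 50 equal-count age bins;
  per bin, Tukey box-plot whiskers are expanded by a factor 1.75 *about
  the bin median* (scaling the whisker's distance from the median, not
  the raw kg value, which would be asymmetric); loess curves (degree 1,
  span 0.5) through the upper and lower limit points define the band.
* **Duplicates.** One row per (cat, date); conflicts keep the first row
  in file order and are logged.
* **Within-cat plausibility.** For cats with three or more visits, the
  interior point whose log-weight deviates most from the chord between
  its neighbours is removed iteratively while the relative deviation
  exceeds 25%, capped at 20% of the cat's rows. A point is only judged
  when its neighbours span at most 20 weeks: growth is concave in
  log-weight, so a chord across a long visit gap under-predicts genuine
  mid-growth weights, and an unwindowed version of this rule measurably
  biased cohort medians downward. The published analysis does not specify
  its within-individual rule; this stage is a declared reconstruction and
  every constant is configurable.
* **Trial successive drops.** For the six zoometric measures that can
  only grow (height, chest depth, length, elbow width, forelimb,
  hindlimb), a drop greater than 10% between successive timepoints marks
  a pair, and the member with the larger |z| across cats at its timepoint
  is removed. Mass, girth and ribcage are exempt because adiposity can
  genuinely shrink them.

# Study 1

**Neuter groups.** Per sex, the neuter-age axis is split at the lower
quartile, median and upper quartile of all observed neuter ages (type-7
linear-interpolation quantiles, pinned for determinism). Group 1 spans
from 0, so it contains only cats neutered inside it; groups 2-4
additionally share all sexually-intact data up to their lower bounds —
the subsets deliberately overlap. Years are 365.25 days; ages are
week-valued reals (days / 7).

**Trajectories.** Each subset gets its own BCCG fit; its 25th/50th/75th
centile curves are converted to z-scores of the reference standard. The
*upward inclination* is the median-centile z at the end of growth
(default 78 weeks, configurable) minus its value at the group's median
observed neuter age; measuring from zero instead is available as an
option since the published description is ambiguous on the reference
point.

**Pre/post model.** For each neutered cat: z at the last visit strictly
before neutering and at the last visit afterwards, kept only when both
exist and are at least 13 weeks (3 months) apart. The linear model is
`post_z ~ 0 + cell + pre_z` with one cell per sex-by-group combination,
so each cell coefficient is the estimated post-neutering z for a cat at
the median weight (pre-z = 0). The published model lists main effects but
reports per-cell means; the full interaction parametrization is the
declared reconstruction that makes those cells estimable. Multiplicity is
controlled by single-step max-|t| adjustment (via `multcomp`) over the
restricted family actually compared — groups within sex and sexes within
group, 16 contrasts — and compact letter displays are built per family by
insert-and-absorb. A Monte-Carlo max-|t| oracle (`maxTAdjustedPMC`)
cross-checks the adjusted p-values in the tests.

# Study 2

**Model.** With $y^*$ the log-transformed, z-standardized value of
measure $m$ for cat $c$ (litter $l$) at week $w$:

$$ y^*_{c,w,m} = x_{g(c),w}^\top \beta_m + u_{l,m} + v_{c,m} +
   \varepsilon_{c,w,m}, $$

where $x$ encodes group, week and their interaction (8 columns),
$\beta_m \sim N(0, 4^2)$ per coefficient (the analysis convention: wide
enough to cover the standardized data, proper enough to stabilize an
11-litter fit), $u_l \sim N_{11}(0, \Sigma_L)$ and
$v_c \sim N_{11}(0, \Sigma_C)$ carry cross-measure correlation at the
litter and cat level, and residuals are independent across measures given
those effects. Standardization constants are stored per measure for exact
back-transformation.

**Priors and sampler.** The model is fully conjugate, so the package uses
an exact blocked Gibbs sampler: per measure, $(\beta_m, u_{\cdot,m},
v_{\cdot,m})$ are drawn jointly from their multivariate-normal full
conditional (the joint block decouples the intercept from the
random-effect means and mixes far better than one-at-a-time scans);
$\Sigma_L, \Sigma_C$ get inverse-Wishart priors (df $= 13$, scale
$0.1\,I$) and conjugate updates; residual variances get inverse-gamma
(2, 0.5) updates; missing responses are latent parameters redrawn each
sweep, which is exactly "imputation during model fitting". Conjugacy at
both covariance levels is why inverse-Wishart was chosen over scale
Cholesky/LKJ parametrizations, which would need a gradient-based sampler;
with 11 litters the weakly-informative scale matters more than the
family. The default schedule is 4 chains of 10,000 sweeps, 5,000 warm-up,
thinned 1-in-5: exactly 4,000 retained draws. Split-R-hat and bulk ESS
are computed for all 88 fixed effects and gate the fit at R-hat < 1.05.

**Fold changes.** For each draw, group and week, the fold change from the
baseline week (labelled 11 weeks, the first measurement wave; the label
is configurable because printed summaries elsewhere call it 10 weeks) is
$\exp(s_m(\eta_{g,w} - \eta_{g,\mathrm{base}}))$ — a ratio of geometric
means — and the fold-change *ratio* is neutered over intact, so values
above 1 mean the neutered group changed more. Summaries report posterior
means, central 95% intervals, and simultaneous intervals.

**Simultaneous intervals.** The sup-t construction finds the smallest $k$
such that the per-quantity intervals $\text{mean} \pm k\,\text{SD}$
jointly contain at least 95% of draws; degenerate (zero-SD) quantities
become point intervals outside the search. For independent Gaussian
families this reproduces the Sidak-matched quantile; for perfectly
correlated families it collapses to the pointwise interval; it is never
narrower than pointwise.

**Posterior predictive checks.** `posteriorPredictiveCheck()` simulates
replicate trials (new litter/cat effects from the covariance draws) from
40 evenly spaced retained draws and exports kernel-density traces per
measure and week alongside the observed trace.

# What the generators emulate — and what they do not

`simulateClinic()` draws: a stable cat-level z offset (SD 0.8) around
smooth Gompertz-shaped sex-specific standards; visit ages from a
preventative-care milestone mixture (clusters near 8, 12, 16, 24, 52, 80,
104 and 120 weeks plus a uniform background over 5-130 weeks); lognormal
neuter ages with paper-like quartiles (medians about 23/25 weeks for
males/females); a post-neuter z shift that is larger in females (default
amplitudes 1.3 vs 0.35), decays linearly with neuter age, and ramps in
linearly from the neuter date to the end of growth (78 weeks) — the
simplest shape consistent with the roughly linear post-neuter inclination
seen in clinic trajectories; multiplicative log-normal weighing noise
(SD 0.06); and measurement artifacts at configurable rates
(whole-pound rounding 15%, rolled-over weights 2%, carrier weighings 2%).
Body-condition categories are driven by the cat's current latent z
(heavy above +2.2), so the eligibility filter genuinely selects against
cats whose z drifts upward — the same reason the clinic estimates are
acknowledged under-estimates; a switch (`bcsDependsOnZ = FALSE`) decouples
them when an experiment needs an unconfounded estimand. Truth tables
expose every latent quantity per record.

`simulateTrial()` draws 11-measure littermate pairs with exchangeable
cross-measure covariance at litter (SD 0.04, correlation 0.4) and cat
(SD 0.06, correlation 0.5) level, per-measure residual SDs (largest for
fat mass), group-by-week effects concentrated on weight, fat, lean, girth
and ribcage — final-week fold-change ratios 1.34 / 1.91 / 1.23 / 1.20 /
1.18, the published effect regime, half-realized at week 30 and absent at
the pre-neutering weeks — and 0.3% missingness completely at random
(matching 3 missing values in 968).

Not emulated: seasonality and calendar effects, breed mixture, clinic
scale precision and operator effects, real visit-frequency demographics
beyond the milestone mixture, informative missingness, and DEXA
measurement error structure. Passing tests therefore demonstrate that the
pipelines recover known truth under a realistic but idealized data
process, not that any specific clinical estimate is correct.

# Validation experiments and problem sizes

The package ships its operating-characteristic studies as exported
functions, run by both the test suite and `scripts/acceptance.R`:

* `nullTrajectoryExperiment()` — full Study-1 pipeline on 80,000
  effect-free cats; all 8 inclinations must stay within $\pm 0.1$ z. The
  population is deliberately large: per-subset mid-age coverage mirrors
  clinic sparsity, and at smaller n Monte-Carlo noise in a maximum over 8
  cohorts masquerades as a spurious effect, whereas larger n only makes
  the bias check stricter.
* `nullTypeIExperiment()` — 20 replicates at 4,000 cats; the adjusted
  analysis should report nothing in at least 95% of them. Note the
  criterion is intrinsically noisy: a perfectly calibrated 5% familywise
  test fails a 19-of-20 bar about a quarter of the time.
* `effectRecoveryExperiment()` — 20 replicates at 7,000 cats with a full
  shift of 1.0 z injected for females; pairs restricted to post-growth
  visits (where the ramp has delivered the full shift) and uninformative
  BCS, so the estimand is pure estimator accuracy; cell sizes land in the
  hundreds-per-cell clinic regime. The mean recovered female group-1
  shift must lie within $\pm 0.1$ of 1.0.
* `doseResponseExperiment()` — steeply decaying shift; estimated cell
  means must decrease across groups 1-4 in at least 90% of replicates.
* `mvmmCoverageExperiment()` — 50 replicate 11-litter trials at a reduced
  schedule (2 chains x 500, 250 warm-up); simultaneous 95% intervals must
  cover the full vector of true ratios, and the injected 1.9 fat-mass
  ratio, in at least 90% of replicates.

# Known limitations

* The BCCG fitter targets growth-reference-sized problems (hundreds to
  tens of thousands of rows); it has no provisions for covariates beyond
  age.
* The within-cat plausibility rule and the pre/post cell parametrization
  are reconstructions of under-specified published procedures; both are
  flagged as such above and kept configurable.
* The Gibbs sampler exploits conjugacy and therefore cannot accommodate
  non-conjugate priors (e.g. LKJ) without replacing the covariance
  updates.
* Fold-change ratios are exactly invariant to the standardization
  constants only because back-transformation uses the stored constants;
  feeding the model externally standardized data without those constants
  would silently change the scale.
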