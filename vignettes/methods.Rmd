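---
title: "Robust estimation of sex differences and similarities in regional brain volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust estimation of sex differences and similarities in regional brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexvoldiff)
```

## The problem

Group comparisons of regional gray-matter volumes are confounded by gross
head size: males have, on average, 10--12% larger total intracranial
volume (TIV), and any regional volume that scales with TIV will show a
"sex difference" that is really a head-size difference. `sexvoldiff`
implements a complete two-track analysis of a per-subject table of
regional volumes (the 18-region SENT_CORE sentence-processing network is
the canonical use case, but any region set works): every analysis is run
twice, once on raw volumes and once after removing TIV variation, and the
two sets of results are compared at the level of effect sizes, model
structure, and classification geometry.

## TIV adjustment: power-corrected proportions

The adjustment is the power-corrected-proportions (PCP) method. For each
region, the exponent $b$ is the OLS slope of $\log(\mathrm{VOL})$ on
$\log(\mathrm{TIV})$ fitted on the entire pooled sample (both sexes), and

$$\mathrm{VOL}_{adj} = \mathrm{VOL} / \mathrm{TIV}^{\,b}.$$

Under a power-law generative model this removes the TIV dependence
exactly; `tiv_variance_explained()` tracks the $R^2$ of the TIV--volume
regression before and after adjustment (volume scale by default; the
log-scale variant sits behind `log_scale = TRUE` — the choice barely
matters for monotone power-law data, and the volume scale is the more
common bookkeeping).

One subtlety the package documents rather than hides: because $b$ is
fitted on the *pooled* sample, a genuine sex offset on the log scale is
partially absorbed into $\hat b$ whenever TIV differs by sex. Under the
reference simulation settings the attenuation factor is about 0.6: a
log-offset $\delta$ realizes an adjusted-scale standardized shift of
roughly $0.6\,\delta/\sigma_\varepsilon$. This is a property of
pooled-slope PCP itself, and it is why the generator's seeded offsets are
calibrated on the *realized* adjusted scale (see below).

Both raw and adjusted volumes are transformed to robust z-scores,
$0.6745\,(x - \mathrm{median})/\mathrm{MAD}$ with the MAD unscaled, so
that decile differences read directly on the Cohen's-$d$ scale.

## The univariate battery

For every region, the female and male robust-z distributions are compared
five ways:

1. a global heteroscedastic rank test (Cliff's dominance method), with
   the location shift reported as the difference of Harrell--Davis
   medians;
2. the $\eta$ overlap index — the area under the pointwise minimum of the
   two kernel density estimates (Gaussian kernel, Silverman bandwidth per
   group, a common grid spanning the pooled range ± 3 bandwidths,
   trapezoid integration), with a percentile-bootstrap CI (1000 reps by
   default);
3. the decile shift function — Harrell--Davis deciles, their differences,
   percentile-bootstrap CIs (4000 reps), and Hochberg control over the
   nine within-region comparisons;
4. Cliff's delta / probability of superiority (exhaustive pair counting,
   ties counted half; the delta CI uses Cliff's consistent variance and
   the bound-respecting asymmetric interval) plus the empirical Cohen's
   U3 — the percent of one group strictly above the other group's
   Harrell--Davis median, with a 2000-rep bootstrap CI;
5. spread and shape — the interquartile ratio (HD quartiles, Wald test on
   the log ratio with a bootstrap SE) and percentile-bootstrap
   comparisons of skewness and kurtosis (plug-in moment estimators;
   kurtosis is non-excess, so Gaussian data sit near 3).

Across the regions, Benjamini--Hochberg FDR is applied within each test
family, and a direction (`F>M` / `M>F` / `none`) is assigned only when
the FDR-adjusted global or delta test is significant. Magnitude labels
use |d| cut points 0.2/0.5/0.8 and |delta| cut points 0.147/0.33/0.474
(configurable).

The TIV-dependence table correlates (Spearman) each region's TIV-$R^2$
with its effect-size estimates. Signed statistics enter oriented toward
the dataset's dominant direction — the convention under which raw-volume
tables show strongly positive correlations — with `orient = "f_minus_m"`
available to keep the package-wide F-minus-M signs. Whether signed or
absolute decile differences should enter was genuinely open; signed is
the default because it preserves direction reversals.

## The multivariate track

**Classification probabilities.** An L2-penalized logistic regression
predicts sex from the region z-scores. The reference (positive) class is
the sex favored by the observed univariate differences — operationally,
the sign of the median Cliff's delta over the FDR-significant regions,
falling back to the all-region median when nothing is significant. (The
all-region median alone is dominated by noise when most regions are null;
restricting to significant regions is what keeps "higher Pclass = larger
volumes" true in practice.) The ridge penalty is selected on the grid
$\{0, 2^{-4}, \dots, 2^{8}\}$ by a corrected-AIC penalty trace,
maximizing $\chi^2_{LR} - 2\,\mathrm{df}_{eff}$ with
$\mathrm{df}_{eff} = \mathrm{tr}\!\left[I(\hat\beta)\,(I(\hat\beta) +
\lambda P)^{-1}\right]$. Wald statistics use the sandwich covariance of
the penalized fit and are flagged as approximate; coefficient p-values
are FDR-adjusted within the model.

Discrimination (Nagelkerke $R^2$, C-index, Somers' $D_{xy} = 2(C-0.5)$)
is reported apparent and optimism-corrected by Harrell's bootstrap
(refit on each resample at the selected penalty; 200 reps stand-alone, 50
in the pipeline default). The per-subject probabilities (Pclass scores)
are then treated as a continuous outcome and pushed through the same
univariate battery, plus: accuracy at the 0.5 cutoff (per-sex rates and
their balanced mean), per-sex CDF deciles, the all-pairwise
reference-minus-other difference distribution (HD deciles, percent
favoring the reference with a subject-level bootstrap CI, and — since
Pclass lives on [0, 1] — a percent-of-maximum-possible reading), and a
nomogram table whose per-predictor point scales are proportional to
$|\beta_j| \times \mathrm{range}_j$, oriented so points accumulate toward
the reference sex.

**Projection onto the between-centers line.** Independently of any model,
each subject is projected onto the line joining the two groups' marginal
Harrell--Davis median centers; the signed distances are analysed with the
same toolbox, plus the $Q$ statistic (per-group KDE, each observation
assigned to the higher density, mean of the two correct rates) and an
explained-variance $R^2$ (between-group over total variance of the
distances). The center choice is configurable (`median`, `mean`); the
marginal-median centers are robust but only approximately
rotation-equivariant — the `mean` option restores exact equivariance when
that matters.

A data-chosen projection is optimistic: in 18 dimensions the estimated
direction aligns with sampling noise, and under the null the plain PS
interval badly undercovers (we measured ~2.5% coverage at 100 per sex).
`projection_ps_split()` is the confirmatory path: the direction is
estimated from a seeded half of each group and Cliff inference runs on
the held-out halves only, restoring nominal coverage (~95% measured).
The pipeline reports both; the plain quantities remain the descriptive
ones, comparable with the Pclass column.

**Cross-method comparison.** PS for both sexes, Cliff's delta with CI,
overlap, U3, $Q$ and $R^2$ are computed from each score vector
side-by-side, both oriented toward the reference sex (projected distances
grow toward the M center by construction and are negated when the
reference is F). Score--score and score--TIV correlations use Pearson's
r with HC4 heteroscedasticity-consistent standard errors and a symmetric
bootstrap-t ($r \pm t^*_{|t|,0.95}\,\mathrm{se}$); the symmetric form
holds its coverage visibly better than the equal-tailed one under strong
leverage-dependent noise at n = 100, though both remain slightly below
nominal in the most extreme case (noise exactly zero at the design
center).

**Structure reports.** Pairwise absolute Spearman correlations of the
region coefficients across the fitted models (TIV-augmented models
excluded their TIV coefficient), per-model correlations of coefficients
with the univariate medians' difference / delta / U3, and the
intersection decomposition of FDR-significant predictors across models.

## The synthetic cohort generator

No human data ship with the package; the generator produces cohorts with
exactly the structure the analysis assumes, with known ground truth:

$$\log \mathrm{TIV}_i \sim N(\mu_{sex}, \sigma_T^2), \qquad
\log \mathrm{VOL}_{ij} = \log a_j + b_j \log \mathrm{TIV}_i +
\delta_j\,[sex_i = F] + \lambda_j u_i + \varepsilon_{ij}.$$

Defaults (chosen once, as a realistic young-adult cohort): 300 subjects
per sex; TIV centered at 1450 ml with a 12% male advantage
($\mu_M - \mu_F = 0.12$ on the log scale) and within-sex log-sd 0.075;
allometric exponents 0.8 (the reference simulation,
`study_cohort_spec()`, spreads them 0.6--1.0 so regions carry different
amounts of head-size signal); region scales giving 2--20 ml expected
volumes; residual log-sd 0.15 (0.12 in the reference simulation); no
residual correlation by default, with a single common-factor loading
$\lambda_j$ available to induce it for multivariate stress tests. The
sex offset $\delta_j$ acts on the log scale, so it survives any
proportional TIV adjustment — ground truth for recovery tests is
unambiguous. `study_cohort_spec()` seeds $\delta = 0.06$ in `T2_3` and
`f2_2` only, which — after the pooled-slope attenuation described above —
realizes an adjusted-scale Cliff's delta near 0.15, the scale of small
but robust regional effects.

What the generator does *not* emulate: age and education structure,
family/twin relatedness, scanner and site effects, non-power-law
allometry, heavy-tailed or skewed regional distributions, and spatially
structured residual correlation. Passing tests therefore demonstrate that
the estimators and the pipeline do what they claim under the stated
model, not that any particular empirical cohort behaves this way.

## Numerical choices and degenerate inputs

Determinism: one master seed drives everything; each stochastic stage
(and each region within a battery) receives a child seed from a single
`derive_seeds()` draw, so stages can be re-run in isolation and full
reruns are byte-identical. Bootstrap operations sort each group before
resampling — the estimators are permutation-symmetric, and the canonical
order makes CIs invariant to subject ordering.

Ties in pair counting contribute 0.5; U3 uses strict inequality against
the reference HD median (immaterial for continuous data, fixed for
reproducibility); zero-MAD regions, constant TIV, coincident projection
centers, rank-deficient or constant predictors, and out-of-range
probabilities all raise errors naming the offending region or column.
Percentile-bootstrap p-values are
$2\min(P^*(\hat\theta^* < 0), P^*(\hat\theta^* > 0))$. Complete
separation at $\lambda = 0$ fails over to the penalized grid points; an
all-zero coefficient vector makes the nomogram an error rather than a
flat drawing.

Problem sizes used by the test-suite simulations (chosen to make the
checks sharp while keeping a full run comfortable on a laptop): null
calibration at 100 per sex with 200--250 replicates; closed-form Gaussian
limits at 2000 per group; recovery experiments at 300 per sex over 20
seeds; the end-to-end run at 600 subjects with reduced bootstrap reps
(500/250/250/250) and 50 validation refits.

## Known limitations

* The pooled-slope PCP attenuation means injected and estimated
  adjusted-scale effects are smaller than the generative log offsets;
  sex-stratified exponent fitting would avoid this but is deliberately
  not the default, because the pooled fit is the method as defined.
* Wald tests on penalized coefficients are approximate; their FDR flags
  should be read as a screening device, which is also how the
  intersection analysis treats them.
* The plain projection PS interval is descriptive, not confirmatory; use
  `projection_ps_split()` for calibrated inference.
* HC4 bootstrap-t intervals can run a few points below nominal coverage
  at n ≈ 100 under extreme heteroscedasticity.
* The $Q$ statistic uses fixed-bandwidth KDE; an adaptive kernel would be
  slightly more efficient for very skewed score distributions.
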