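---
title: "Models and methods behind rangesqueeze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rangesqueeze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangesqueeze)
```

## The scientific question

Two opposing predictions link species' range sizes to temporal temperature
variability. The classical view (Stevens' hypothesis) holds that species
in thermally variable places evolve broad tolerances and therefore occupy
broad ranges: a positive range-size/variability relationship. The
*temperature range squeeze* view starts from lethal temperature limits
instead: at any elevation, temperatures fluctuate over time, and a species
persists only where it never meets a lethal extreme. The wider the
fluctuation, the narrower the band of elevations in which neither the
cold nor the heat limit is ever crossed — predicting a *negative*
relationship. `suitable_habitat_span()` expresses the geometry: with
tolerance window $[T_l, T_u]$, temporal fluctuation width $\Delta T$ and a
constant lapse rate $\ell$ (degC per 100 m),

$$\mathrm{span} = \max(0,\; T_u - T_l - \Delta T)\,/\,\ell \times 100\ \mathrm{m},$$

which is non-increasing in $\Delta T$. The lapse rate is read as degC per
100 m; with a 0–20 degC tolerance, no fluctuation and $\ell = 0.5$, the
suitable span is 4000 m. The package tests the two predictions against
species' elevation range sizes (max minus min recorded elevation per
species per mountain) across and within mountains, using three
variability covariates: diurnal temperature range (DTR, the mean daily
max–min temperature), temperature seasonality (TS, the SD of monthly mean
temperatures) and the long-term change in mean annual temperature over
the last two millennia (`dmat`, the max-minus-min of a series of 30-year
means).

## The two hierarchical models

**Global (across mountains).** Species $i$ in mountain $s$ contributes its
natural-log range size $y_i$:

$$y_i \sim N(\alpha_{site[s_i]},\ \sigma^2_{RS}), \qquad
\alpha_{site} \sim N(\alpha_V + \beta_V V_{site},\ \sigma^2_{site}),$$

with $V_{site}$ a mountain-level covariate (band-mean DTR or TS over the
standardized domain, or `dmat`). Priors follow the BUGS convention in
which the second argument of a normal is a *precision*: $\alpha_V, \beta_V
\sim N(0, 10^{-6})$ (i.e. variance $10^6$, effectively flat) and
$\Gamma(10^{-3}, 10^{-3})$ priors on both precisions
$1/\sigma^2_{RS}, 1/\sigma^2_{site}$. Variants replace the site-level line
with two covariates plus their product (`fit_global_interaction()`; both
main effects are always included alongside the product, the standard
identifiability practice, and pairs with absolute correlation above a
guard — default 0.6 — are warned about because strongly collinear
interactions are untrustworthy) or with separate island/continental
intercepts and slopes via cell-means coding (`fit_global_by_landtype()`).

**Local (within mountains).** On the original, non-standardized gradients,
with $v_i$ the covariate at species $i$'s range midpoint:

$$y_i \sim N(\alpha[s_i] + \beta[s_i]\, v_i,\ \sigma^2),$$

with flat normal priors on every intercept and slope and a single shared
residual variance $\sigma^2$ with a $\Gamma(10^{-3}, 10^{-3})$ prior on
its precision. Mountains whose covariate does not vary between at least
two species cannot identify a slope; they are flagged and excluded from
the fit. `dmat` is refused as a local covariate: one value exists per
mountain, so it cannot vary along a gradient.

## Sampling

Both models are fully conjugate, so `fit_global()` and `fit_local()` use
blocked Gibbs samplers with closed-form full conditionals: site means (or
per-site intercept/slope pairs, drawn jointly from their bivariate normal
conditional) are updated in one vectorised sweep, regression coefficients
from their multivariate normal conditional, and precisions from gamma
conditionals. Initial values are moment-based (empirical site means,
least squares on them, method-of-moments precisions), so chains start in
the bulk of the posterior. Defaults mirror the study design: 3 chains,
50,000 iterations, 20,000 burn-in, and after the configured iterations
chains are extended in 10,000-iteration increments (at most 5) until the
effective sample size of every parameter reaches `target_ess` (default
3,000). Everything is deterministic given `mcmc_config(seed = )`.

Covariates are used on their natural scale: with flat priors the fit is
equivariant to location/scale changes, so standardization is a numerical
convenience, not a modelling choice; analyses that need a
better-conditioned intercept (e.g. sampler validation) simply center the
covariate column before building the model data.

`fit_global_reference()` is an independent validation sampler for the same
posterior: the site effects *and* the regression coefficients are
integrated out analytically (the marginal likelihood of the site means
given the two precisions is closed-form, with the flat coefficient prior
entering as a rank-p covariance update), a componentwise random-walk
Metropolis chain explores the two-dimensional marginal of the log
precisions, and coefficients and site effects are recovered by exact
conditional draws. Marginalizing is essential: with a diffuse gamma prior
and few sites the joint posterior is a funnel (site-variance excursions
flatten the coefficient conditionals), and a fixed-scale random walk in
the joint space mixes arbitrarily badly there, while the two remaining
coordinates have clean unimodal profiles.

### A caution about three-site posteriors

`sampler_crosscheck_study()` compares the two samplers on a deliberately
tiny instance (3 mountains, 10 species each). With $S$ sites the
posterior of $1/\sigma^2_{site}$ has a gamma-like shape of roughly
$10^{-3} + S/2$; at $S = 3$ that is about 1.5, so $\sigma^2_{site}$ has
*infinite posterior variance* and its raw posterior mean admits no
finite-variance Monte Carlo estimator — no sampler can pin it down. The
study therefore compares the variances through the posterior *median* of
their logarithm — the raw mean has no finite-variance Monte Carlo
estimator, and even the log-scale mean converges slowly because with
$S - p = 1$ residual degree of freedom the large-variance tail thins only
like $\exp(\tfrac{1}{2}\log\tau)$, while the median is density-based and
tail-insensitive — centers the covariate so the intercept is identified
at the data rather than extrapolated to covariate zero, and
generates the instance with a between-site SD of 0.05 and a within-site
SD of 0.01. Those two numbers are chosen jointly: the heavy upper tail
of $\sigma^2_{site}$ scales with $S\sigma^2_{site}$ (so the between-site
SD must be small), while the weakly-penalized $\sigma^2 \to 0$ plateau
disappears only when $\sigma^2_{site}$ sits far above the noise floor
$\sigma^2_{RS}/n_s$ (so the within-site SD must be smaller still; here
the ratio is 250). Both chains are run long (1.2 million Gibbs draws,
2.4 million Metropolis iterations) because agreement is meant to measure
implementation correctness, not sampling noise.

## Data rules before modelling

The preprocessing stages run strictly in order — validate, filter
mountains, standardize, exclusion zones, transform — and
`preprocess_dataset()` enforces it (later stages reject records that
earlier stages would have fixed or removed).

* **Validation** (`validate_records()`): rows with min above max, any
  elevation above 6500 m (the ceiling for vascular plants), or non-finite
  values are logged with reason codes, not errors — such rows are data
  entry artifacts.
* **Mountain filters** (`filter_mountains()`): a mountain is kept when at
  most 25% of its species are singletons (range size 0; an excess signals
  under-sampling) *and* its sampled sections have no gap wider than 500 m.
  "Sampled sections" are the union of the species' elevation intervals —
  the only construction available when only ranges, not occurrences, are
  known; singletons contribute points. Both rules use the full
  pre-standardization data.
* **Standardization** (`standardize_gradient()`): to compare mountains of
  different spans, each gradient is trimmed to a fixed length anchored at
  its top (e.g. a 0–5100 m gradient standardized to 2000 m becomes
  3100–5100 m); bottom anchoring mirrors the rule. Ranges crossing the
  new boundary are truncated to it; a range reduced to a single boundary
  point is kept and counts as a singleton downstream; species entirely
  outside are dropped. Mountains shorter than the target length are
  excluded and logged — this is how sample sizes shrink as the
  standardized length grows.
* **Exclusion zones** (`apply_exclusion_zones()`): species found
  exclusively within $E$ meters of either end of the domain are removed,
  because edge-squeezed ranges are truncated fractions of potential
  ranges. Containment is strict: a range exactly touching a zone's inner
  edge is kept. $E = 0$ is the identity.
* **Transform** (`transform_range_sizes()`): singletons (range 0) are set
  to 10 m — the smallest positive range observable at 100 m data
  precision — and everything is natural-log transformed. Only exact zeros
  are floored.

Elevations are handled as floats in meters and never re-rounded. Climate
bands are half-open $[l, l + 100)$ anchored at 0 m a.s.l., so no pixel or
midpoint is counted twice; a species midpoint exactly on a band boundary
belongs to the upper band. Mountain-level covariates are unweighted means
over the bands lying entirely within the (standardized) domain — each
band counts once; a pixel-weighted option exists behind
`weight = "pixels"`. `dmat` is computed once per mountain from its paleo
series, independent of elevation.

## The synthetic world

`generate_world()` emulates the statistical structure the models assume,
not the physics of real rasters or reconstructions. Defaults describe the
kind of dataset the package targets: 44 mountains of which 15 are
islands, spans 1500–6000 m, island DTR centered at 8 degC versus 13 degC
for continental mountains (ocean buffering), TS between 0.5 and 8 degC, a
0.5 degC / 100 m lapse rate, about 2000 species ranges per mountain and a
15% singleton fraction (comfortably under the 25% exclusion rule). DTR
and TS drift mildly with elevation (0.3 and 0.4 degC per km) so the local
model has an identifiable within-mountain covariate. Paleo series are
Gaussian random walks rescaled to an exact max-minus-min amplitude
(0.4–1.5 degC): only that amplitude matters downstream. Ranges are
back-transformed from the generated log sizes and placed uniformly among
the positions where they fit inside the domain, so range *sizes* follow
the generative law exactly whenever they fit; ranges wider than the
domain are clipped to it. Singletons are made by collapsing a configured
fraction of ranges to their midpoint.

What the generator does *not* emulate: spatial autocorrelation of real
climate rasters, elevation-dependent sampling effort, taxonomic error,
or any correlation between DTR, TS and the paleo amplitude (they are
drawn independently). Passing tests therefore demonstrate that the
pipeline and samplers do what they claim on data meeting the model's
assumptions — not that the assumptions hold for any particular real
mountain.

## Evaluation choices

* **WAIC** is computed from the pointwise log-likelihood over posterior
  draws as $-2\sum_i[\log \bar{p}_i - \mathrm{var}_d(\log p_{di})]$, with
  a standard error from the spread of pointwise contributions. By
  default the log-likelihood of every 10th kept draw is stored
  (`loglik_thin`), which keeps memory bounded without noticeably
  affecting WAIC/LOO at the draw counts used.
* **LOO** is Pareto-smoothed importance sampling: per observation the
  largest 20% of importance ratios are replaced by quantiles of a fitted
  generalized Pareto distribution (profile-likelihood fit with a weak
  prior pulling the shape toward 0.5 in small tails), truncated at the
  raw maximum; tail shapes above 0.7 are flagged. `exact_loo_global()`
  provides the brute-force refit reference used to validate it.
* **R-hat** is the classic split-chain Gelman–Rubin statistic (not
  rank-normalized), matching the JAGS-era toolchain; the convergence
  gate is 1.01. Note that the split version of the statistic applied to
  two identical copies of a finite stochastic chain is near, not exactly,
  1 — exact unity holds only for constant chains.
* **ESS** combines within-chain autocovariances (FFT) with the
  between-chain variance and truncates by Geyer's initial positive
  sequence rule; a constant chain is reported as its total draw count
  with a warning.
* **Bayesian R²** is not uniquely defined for this model family; the
  package uses, per posterior draw, the variance of fitted site means
  over itself plus the drawn between-site variance, reported as a
  posterior mean — a site-level variance-explained measure in $[0, 1]$.
* Credible intervals are equal-tailed (2.5%, 97.5%) throughout;
  $P(\beta < 0)$ is the fraction of draws strictly below zero; local
  slopes are classed by the sign of the posterior mean and flagged
  low-uncertainty when the 95% interval excludes zero.
* **Posterior predictive checks** simulate replicated datasets from
  thinned posterior draws and report, per site and statistic (mean, SD,
  min, max of log range), the tail probability $P(T_{rep} \ge T_{obs})$,
  flagging values outside (0.025, 0.975).

## Validation studies and the problem sizes used

The `*_study()` functions regenerate everything from scratch at fixed
seeds and are what the package's acceptance checks run:

* `recovery_study()`: 50 worlds of 30 mountains x 100 species with
  $\beta_V = -0.1$, $\sigma_{site} = 0.3$, $\sigma_{RS} = 0.8$, fitted at
  the full default chain settings; reports 95% CI coverage of the slope,
  the bias of the posterior mean (averaged across replicates) relative to
  the average posterior SD, and the worst R-hat / smallest ESS. Recovery
  worlds use wide gradients (4000–6430 m) so that back-transformed ranges
  essentially never hit the domain ends: domain truncation is a real
  feature of such data, but it is exercised and tested in the
  preprocessing suite, and leaving it out here keeps the generative law
  exact so that coverage measures the sampler, not placement artifacts.
* `selection_study()`: 20 worlds of 30 mountains x 25 species in which
  DTR generates the ranges and TS and `dmat` are independent decoys;
  moderate species counts keep partial pooling informative about the
  covariate, which is what WAIC/LOO must detect. Reports how often the
  DTR model attains the lowest WAIC and highest LOO elpd.
* `null_calibration_study()`: 100 worlds with $\beta_V = 0$; $P(\beta<0)$
  should land in [0.025, 0.975] about 95% of the time. Reduced chains
  (2 x 4,000) suffice because only a tail probability is needed.
* `sampler_crosscheck_study()` and `loo_oracle_study()` as described
  above (the LOO study uses a 4 x 5 instance, n = 20, with full
  log-likelihood storage and 30,000 draws so the comparison measures the
  smoothing, not Monte Carlo noise).

## Numerical notes and limitations

Per-iteration Gibbs cost is $O(S)$ via per-site sufficient statistics, so
chain length, not species count, dominates runtime. Designs with one or
two coefficient columns use closed-form scalar/2x2 Cholesky updates; the
general path uses a dense Cholesky. Degenerate inputs fail fast: constant
covariates, rank-deficient interaction designs, a land type with fewer
than two sites, unvalidated records in later pipeline stages. Zero-width
leftovers of truncation are retained as singletons; ties at band or zone
boundaries follow the half-open / strict-containment conventions above.

The package deliberately implements no occurrence cleaning, no taxonomic
name resolution, no raster download or reprojection, and no
probabilistic-programming generality: the two model families above are
the scope. The local model assumes a *shared* residual variance across
mountains; heterogeneous within-mountain noise will be absorbed
imperfectly. And with few sites the diffuse gamma priors leave the
site-level variance weakly identified — the three-site caution above is
the extreme case users should keep in mind when fitting small subsets.
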