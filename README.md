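# rangesqueeze

Bayesian hierarchical analysis of species' elevation range sizes and
temperature variability.

## The problem

Do plants occupy *broader* elevation ranges where temperatures fluctuate
more (the classical expectation: variable climates select for broad
thermal tolerances), or *narrower* ones? The "temperature range squeeze"
argument predicts the opposite sign: at any elevation, temperatures vary
over time, and a species persists only in the band of elevations where it
never meets a lethal extreme — a band that shrinks as thermal
variability grows. With tolerance window $[T_l, T_u]$, temporal
fluctuation width $\Delta T$ and lapse rate $\ell$ (degC / 100 m), the
suitable span is $\max(0, T_u - T_l - \Delta T)/\ell \times 100$ m.

`rangesqueeze` is for ecologists who want to test these predictions on
multi-mountain compilations of species elevation ranges (one min/max
elevation per species per mountain), and for methodologists who want a
fully testable, simulation-backed version of the workflow. It provides:

* a synthetic-data generator producing mountains, 100 m elevation-band
  climate tables (DTR, TS, MAT, AP), paleo temperature series and
  species ranges with the exact statistical structure the models assume;
* the data-hygiene rules used before cross-mountain comparison:
  validation, singleton and sampling-gap filters, gradient
  standardization with truncation, edge exclusion zones, the 10 m
  singleton floor and natural-log transform;
* conjugate blocked Gibbs samplers for the two models, written for this
  package and validated against an independent Metropolis reference
  sampler and closed-form posteriors;
* WAIC, PSIS-LOO (validated against exact refit leave-one-out),
  split-chain R-hat, autocorrelation ESS, posterior predictive checks,
  Bayesian R², slope classification; and
* pipelines: `run_global_analysis()`, `run_local_analysis()`,
  `run_sensitivity_grid()`.

## The models

**Global (across mountains).** For species $i$ in mountain $s$, with
$y_i$ the natural-log range size:

$$y_i \sim N(\alpha_{site[s_i]}, \sigma^2_{RS}), \qquad
\alpha_{site} \sim N(\alpha_V + \beta_V V_{site}, \sigma^2_{site})$$

where $V_{site}$ is a mountain-level covariate (band-mean diurnal
temperature range or temperature seasonality over the standardized
gradient, or the max-minus-min of a 30-year-mean paleo temperature
series). Priors: $\alpha_V, \beta_V \sim N(0, 10^{-6})$ in the BUGS
precision convention (variance $10^6$), and $\Gamma(10^{-3}, 10^{-3})$ on
both precisions. Variants add two-covariate interactions or separate
island/continental intercepts and slopes.

**Local (within mountains).** On the original gradients, with $v_i$ the
covariate at the species' range midpoint:
$y_i \sim N(\alpha[s_i] + \beta[s_i] v_i, \sigma^2)$, flat normal priors
on all intercepts/slopes, one shared residual variance.

## Worked example

```r
library(rangesqueeze)

world <- generate_world(
  world_config(n_mountains = 12, n_species_per_mountain = 150,
               span_range = c(2600, 5500), seed = 7),
  true_parameters(alpha_V = 6, beta_V = -0.12, sigma2_site = 0.04,
                  sigma2_RS = 0.5))

report <- run_global_analysis(
  world,
  standardization_config(length = 2500, exclusion_zone = 250, anchor = "top"),
  mcmc_config(n_chains = 3, n_iter = 6000, burn_in = 2000, target_ess = 0,
              seed = 1),
  covariates = c("dtr", "ts", "dmat"))
print(report)
```

```
Global-scale analysis
  mountains retained: 12; species: 1123
  slope summaries:
 covariate beta_mean beta_sd  lower   upper prob_negative    r2
       dtr   -0.1070  0.0168 -0.140 -0.0733         1.000 0.851
        ts   -0.0917  0.0817 -0.253  0.0673         0.882 0.168
      dmat   -0.7451  0.4260 -1.597  0.0965         0.962 0.275
  model comparison (best WAIC first):
 model waic waic_se p_waic elpd_loo loo_se max_pareto_k n_flagged
   dtr 3339   46.66  9.692    -1670  23.33       0.2118         0
  dmat 3340   46.80 11.962    -1670  23.40       0.2169         0
    ts 3340   46.85 12.074    -1670  23.43       0.2169         0
```

The world was built with diurnal temperature range (DTR) driving range
sizes at slope −0.12. The report shows what the analysis should find:
preprocessing standardized all 12 gradients to 2500 m and kept 1123 of
1800 species after truncation and 250 m exclusion zones; the DTR slope is
recovered (posterior mean −0.107, 95% interval excluding 0, P(β<0) = 1,
site-level R² 0.85) while the decoy covariates are weaker and more
uncertain; and the DTR model attains the best (lowest) WAIC and best
(highest) LOO elpd. `run_local_analysis()` produces the within-mountain
counterpart (per-mountain slope signs with uncertainty classes), and
`run_sensitivity_grid()` repeats the global fit over standardization
lengths x exclusion zones x anchoring to show the conclusions do not
hinge on those choices.

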