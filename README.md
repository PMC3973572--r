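# nestmosaic

Great-ape nest-survey analysis for fragmented forest–savannah
landscapes, in R.

Nest counts are often the only practical evidence of bonobo or
chimpanzee populations. `nestmosaic` implements, as a tested and
reusable pipeline, the full inference chain of a two-community bonobo
nest-survey programme:

* **Distance sampling** of perpendicular nest distances with a
  half-normal + cosine detection function `g(x)`, detection-probability
  truncation (`g(w) = 0.15`), effective strip width
  `ESW = ∫₀ʷ g(x) dx`, and stratified densities
  `D̂ = n / (2·L·ESW) / (rate × prop. builders × decay time)` with
  log-normal confidence limits (conversion constants: 1.37
  nests·builder⁻¹·day⁻¹, 0.75 nest-builders).
* **Nest decay time** from logistic survival of revisited fresh nests,
  `S(t) = logit⁻¹(β₀ + β₁t)`, with mean `log(1 + e^{β₀})/|β₁|` and a
  site-stratified nest bootstrap for confidence intervals.
* **Between-year dynamics**: zero-inflated negative binomial models of
  per-transect counts (offsets `log L` and `log 1/L`), likelihood-ratio
  year tests, and a Gaussian-kernel spatial **autocovariate** with
  a likelihood-profiled bandwidth — including a parametric-bootstrap
  calibration of the term's significance (the naive Wald z is badly
  anticonservative for self-derived covariates; see the methods
  vignette).
* **Fruit phenology**: basal-area-weighted fleshy-fruit indices,
  Box-Cox normalisation, sine/cosine seasonality with a forest contrast
  and temporal autocovariate, F-tests.
* **Nesting-site covariates**: permutation chi-square + exact binomial
  tests for preferred nesting-tree species, village influence, a
  questionnaire-based human-forest-use index, 30-day rainfall, fruit
  availability at site and forest scale, and a time-interpolated
  community-size offset.
* **Social cohesiveness**: negative binomial models of nest-group size
  under one- vs two-community hypotheses with `log(builders)` offsets,
  joint spatio-temporal autocovariate bandwidths, and AICc comparison.

The original field data are unreleased, so a synthetic-landscape
generator (two communities, clustered nest deposition, half-normal
detection, logistic decay, sinusoidal phenology, village questionnaires)
stands in for them at study scale; all calibration tests run against it.

## Worked example

```r
library(nestmosaic)
library(dplyr)

# 1. decay study: 610 synthetic nests, weekly revisits, nest bootstrap
histories <- simulate_decay_histories(n_nests = 610, seed = 2026)
decay <- bootstrap_decay(histories, n_boot = 1000, seed = 2026)
decay
#> Mean nest decay time: 180.3 days (bootstrap 95% CI 174.5-186.2, n_boot = 1000)
#>   logistic beta0 = 4.451, beta1 = -0.02475 /day

# 2. nest survey: fit detection, truncate at g(w) = 0.15, refit
survey <- simulate_survey(seed = 2026)
distances <- unlist(survey$distances_m)
fit0 <- fit_detection(distances, truncation_w_m = 35)
trunc <- truncate_by_detection(fit0, distances, threshold = 0.15)
trunc$fit
#> Detection function (halfnorm): sigma = 11.62 m, w = 22.8 m
#>   ESW = 13.83 m, mean p = 0.607, AIC = 6628.36, n = 1102

# 3. stratified density and abundance
constants <- conversion_constants(decay_days = decay$mean_days)
density <- density_by_stratum(survey, trunc$fit, constants,
                              cv_decay = decay$cv)
density |> filter(stratum != "Lokoso&Mankere") |>
  select(stratum, year, n, ind_density_km2, lcl, ucl, abundance_n)
#>   stratum  year     n ind_density_km2    lcl   ucl abundance_n
#> 1 Mpelu    2011   276           0.496 0.342  0.720          27
#> 2 Mpelu    2012    82           0.147 0.0794 0.274           8
#> 3 Mpelu    2013   184           0.331 0.211  0.518          18
#> 4 Nkala    2011   186           0.559 0.342  0.914          18
#> 5 Nkala    2012   167           0.502 0.324  0.777          16
#> 6 Nkala    2013   207           0.622 0.422  0.918          20

stratified_abundance(density)
#>   ind_density_km2 cv_pct   lcl   ucl area_km2 abundance_n n_lcl n_ucl
#> 1           0.382   9.39 0.318 0.459     93.8          36    30    43
```

The decay time (~180 d) and truncation (~23 m at the synthetic 12 m
detection scale) are estimates from this one synthetic realisation; the
per-stratum densities track the generator's builder numbers (e.g. the
Mpelu 2012 dip), and the area-weighted global estimate of ~36
individuals over 93.8 km² corresponds to the generating 0.75 × builders
populations.

```r
# 4. one community or two? AICc on the same nesting sites
sites <- simulate_nesting_sites("two_communities", seed = 2026)
compare_hypotheses(fit_cohesion(sites, "one_community"),
                   fit_cohesion(sites, "two_communities"))
#>   aicc_model1 aicc_model2 delta_aicc winner       
#> 1        449.        450.      -1.24 one_community
```

For this single realisation the two hypotheses are nearly
indistinguishable (|ΔAICc| ≈ 1, a tie by conventional AIC reading —
and here the tie breaks the wrong way); across 200 replicate synthetic
datasets the generating two-community hypothesis wins about 85% of the
time, which is what the acceptance suite verifies.

`run_pipeline(pipeline_config(seed = 1))` chains every stage —
synthetic data, decay, distance sampling, ZINB dynamics with bandwidth
profiling, phenology, tree-preference tests and the cohesion
comparison — into one reproducible report bundle. `tidy()`/`glance()`
methods and `plot_detection()`, `plot_density()`,
`plot_bandwidth_profile()` and `autoplot()` cover the result types.

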