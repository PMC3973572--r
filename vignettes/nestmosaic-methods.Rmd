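---
title: "Models and methods behind nestmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nestmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestmosaic)
```

# The scientific problem

Great apes build a fresh sleeping nest nearly every night, and in
landscapes where the animals themselves are rarely seen, standing nests
are the main window onto population density and social behaviour.
`nestmosaic` implements the full inference chain for a bonobo
(*Pan paniscus*) nest-survey programme in a forest–savannah mosaic with
two putative communities (here labelled Nkala and Mpelu, plus a small
unoccupied stratum):

1. line-transect **distance sampling** of nests, converted to individual
   density through nest production and decay constants;
2. a **nest decay time** estimated from longitudinal revisits of marked
   fresh nests;
3. **zero-inflated negative binomial (ZINB)** models of between-year
   variation in per-transect nest counts, with a Gaussian-kernel spatial
   autocovariate whose bandwidth is profiled against the likelihood;
4. a **seasonality model of fleshy-fruit availability** built from plot
   phenology and basal areas;
5. **per-nesting-site covariates** (preferred nesting-tree density,
   fruit availability at two scales, rainfall, village influence, human
   forest use, and an interpolated community-size offset); and
6. **negative binomial models of nest-group size** under one- versus
   two-community hypotheses, compared by small-sample-corrected AIC
   (AICc).

The original field data are not publicly released, so the package ships
a synthetic-landscape generator whose defaults reproduce the study's
design constants (stratum areas, transect layout, survey effort,
conversion constants, community sizes). Every stage of the pipeline is
exercised, and its statistical calibration tested, on that generator.

# Distance sampling

Perpendicular distances $x$ of detected nests from the transect line are
modelled with a half-normal key and optional cosine adjustments,

$$g(x) \propto \exp\!\left(-\frac{x^2}{2\sigma^2}\right)
  \Bigl(1 + \textstyle\sum_j a_j \cos(j\pi x / w)\Bigr),
  \qquad g(0) = 1,$$

fitted by maximum likelihood on $[0, w]$; the number of adjustment terms
(orders 2, 3, ...) is selected by AIC, and candidates whose fitted $g$
goes negative are rejected. A hazard-rate key is available as an
alternative, with the same AIC selection. The effective strip width is
$\mathrm{ESW} = \int_0^w g(x)\,dx$ (adaptive quadrature; the identity
$\bar p \, w = \mathrm{ESW}$ is enforced to quadrature tolerance).

Truncation follows a detection-probability rule: after a provisional
fit, the truncation distance solves $g(w) = 0.15$ by root finding, the
data are truncated there and the function refitted once. Nest density
per stratum–year is the standard estimator
$\hat D_{\mathrm{nest}} = n / (2 L \cdot \mathrm{ESW})$, with
encounter-rate variance from length-weighted between-transect
variability. Individual density divides nest density by the nest
construction rate (1.37 nests · builder⁻¹ · day⁻¹), the proportion of
nest-builders (0.75; infants sleep in their mothers' nests) and the mean
nest decay time. The coefficient of variation combines encounter-rate,
detection (delta method on the ESW) and decay (bootstrap) components;
confidence limits are log-normal, and abundances are densities times
stratum area, rounded to the nearest integer. The global estimate is the
area-weighted mean over strata.

# Nest decay time

Fresh nests marked at construction are revisited on a fixed schedule and
coded `new`, `recent`, `old`, `very old` or `disappeared`. The model is
a binary logistic regression of "still recognisable" on nest age
$t$ (days): $S(t) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 t)$, and the
mean decay time is

$$\bar t = \int_0^\infty S(t)\,dt = \frac{\log(1 + e^{\beta_0})}{|\beta_1|},$$

evaluated both in closed form and by quadrature (the two must agree to
$10^{-6}$ relative; a numerically stable softplus handles extreme
intercepts).

Two implementation points matter:

* **Carry-forward of the absorbing state.** Revisits stop once a nest
  has disappeared. If those later scheduled visits are simply dropped,
  old ages are observed only for long-lived nests and the fitted
  survival curve is biased upward severely (on the generator defaults
  the mean decay time is overestimated by more than a factor of two).
  Because disappearance is absorbing, the nest's status at every later
  scheduled visit is known without visiting; `fit_decay()` therefore
  extends each disappeared nest's record on its own revisit schedule to
  the common follow-up horizon, which makes the age-specific fraction
  present an unbiased estimate of $S(t)$. Censored nests contribute
  only their observed visits.
* **Inference is by bootstrap, not Wald.** Each nest contributes many
  correlated rows, so the binomial pseudo-likelihood's standard errors
  are meaningless. `bootstrap_decay()` resamples nests with replacement,
  stratified by nesting site (respecting within-site correlation), and
  reports the 2.5%/97.5% percentile interval; 1000 replicates by
  default. Internally each replicate is refitted on an aggregated
  per-age binomial table (identical likelihood, ~100× faster).

# Between-year dynamics: ZINB with a residual autocovariate

Per-transect nest counts are frequently zero but occasionally large, so
the count model is zero-inflated negative binomial: a log-link count
part with offset $\log(\text{length})$ and a logit-link zero part with
offset $\log(1/\text{length})$, with survey year as a categorical
predictor in both parts. Fits use `glmmTMB`; a lean internal optimiser
of the same likelihood (`engine = "internal"`) is provided for
simulation studies that need thousands of refits, and the two engines
are cross-checked in the test suite. Year effects are tested by
likelihood-ratio tests between nested fits, and releveling the year
factor provides the remaining pairwise contrasts (the likelihood is
invariant). Leave-one-out refits (`jackknife_influence()`) screen for
influential transects.

Spatial autocorrelation is absorbed by an **autocovariate**: for unit
$i$, the Gaussian-kernel-weighted average of all *other* units'
response-scale residuals from the no-autocovariate model,

$$\mathrm{ac}_i = \frac{\sum_{j \ne i} \phi(d_{ij}; \mathrm{sd}) r_j}
  {\sum_{j \ne i} \phi(d_{ij}; \mathrm{sd})},$$

entered into the count part only, with the kernel SD chosen to maximise
the refit's likelihood.

Two properties of this construction deserve care, and the package
handles both explicitly:

* **The Wald z of the autocovariate is not standard normal under the
  null.** The maximum-likelihood score equations tie each unit's
  residual (negatively) to the weighted average of the others', so even
  for spatially independent data the term looks "significant" far more
  often than $\alpha$ (about 30% at $|z| \ge 2$ in our null
  simulations). `ac_significance()` calibrates the test by parametric
  bootstrap: data are simulated from the fitted no-autocovariate model,
  the *entire* construction (refit, residuals, autocovariate, refit with
  the term) is repeated per replicate, and the observed statistic is
  referred to that null distribution. The calibrated test holds its
  size (5–7% at $\alpha = 0.05$).
* **The raw likelihood profile over the bandwidth drifts to the widest
  kernel on offer**, for any data: the flatter the kernel, the more the
  leave-one-out average becomes a deterministic function of the unit's
  own residual, and the larger the spurious in-sample gain.
  `optimize_bandwidth()` therefore studentises the profile: at each
  candidate SD the observed likelihood gain is centred on the median and
  scaled by the interquartile range of gains obtained on
  parametric-bootstrap null replicates. The studentised profile is flat
  under independence and peaks near the true correlation range when one
  exists; in our recovery simulations (120 units, 2 km field over a
  40 km extent) the selected SD falls within a factor of three of the
  truth in roughly three-quarters of replicates — the bandwidth is
  intrinsically weakly identified when unit spacing is far below the
  correlation range, because the nearest neighbour then carries almost
  all of the signal at any kernel width.

# Fruit phenology

The fleshy-fruit availability index for a unit (forest, plot, site or
the whole area) at a date is
$\sum_{\text{species}} (\text{proportion of trees fruiting}) \times
(\text{basal area, m}^2/\text{ha})$, summed over the configured
fleshy-fruit species set; species lacking a basal-area entry are
excluded with a warning. Basal areas come from stem DBH:
$\sum \pi (\mathrm{DBH}/2)^2$ over the species' stems divided by the
sampled hectares.

Seasonality is modelled on the Box-Cox-transformed index (lambda by
`car::powerTransform`, profile-likelihood maximum) with a Gaussian
linear model on $\sin \theta$ and $\cos \theta$ of the date angle
$\theta = 2\pi \cdot \mathrm{doy} / 365.25$, a forest factor, an
optional forest-by-season interaction, and an optional temporal
autocovariate (the same kernel machinery in one dimension, distance in
days). The amplitude is $\sqrt{b_{\sin}^2 + b_{\cos}^2}$ and the phase
$\operatorname{atan2}(b_{\cos}, b_{\sin})$ — the convention under which
the fitted phase equals the generating phase of
$\text{baseline} + A \sin(\theta + \text{phase})$. Nested comparisons
use extra-sum-of-squares F-tests. Daily fruiting proportions between
biweekly visits take the nearest observation, ties to the earlier one.

# Nesting-site covariates

* **Preferred nesting trees**: the distribution of nesting trees over
  species is compared with species abundance by a chi-square statistic
  whose p-value comes from multinomial permutation under the abundance
  null (add-one corrected), not the chi-square distribution; one-sided
  exact binomial tests per species flag the preferred set at
  $\alpha = 0.05$. The density of preferred species at a site counts
  preferred stems among the site's nest and control trees over a
  fixed-radius disc (default 30 m radius, 0.283 ha — the site's
  reference area is a convention and is exposed as an argument).
* **Village influence**: $\sum_v \mathrm{pop}_v / d_v$ with distances in
  km.
* **Human forest use**: for each village and activity, the per-person
  probability of entering the region (daily activity frequency divided
  by the number of regions the person visits), summed over interviewed
  performers who visit the region and divided by the number of
  interviewed performers, then scaled by the gender-matched census adult
  count and the region area (km²) and summed over villages and
  activities. Gender constraints (e.g. hunting is men-only) are enforced
  by the activity table. The index is log-transformed before modelling.
* **Rainfall**: the sum over the 30 days strictly before nest building
  (a total, not a mean; configurable), with a gap warning when more than
  20% of window days are missing.
* **Fruit availability** at the site (instantaneous, site trees only)
  and in the forest (per-species mean of daily proportions over the 14
  days before building, times basal area).
* **Community-size offset**: the nest-builder estimates from the surveys
  before and after the build date, combined with inverse-gap weights —
  equivalently linear interpolation in time; outside the survey span the
  nearest estimate is used and flagged.

All quantitative predictors are z-transformed (sample SD) so that
coefficients are per predictor SD.

# Cohesiveness: one community or two?

Nest counts per nesting site are modelled by negative binomial GLMs
(log link, `MASS::glm.nb`) on the six predictors above with
$\log(\text{builders})$ as offset. The one-community model uses the
summed builders of both forests and an area-wide fruit index; the
two-community model uses forest-specific builders and fruit. The two
hypotheses are compared by AICc,
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, on the same sites. The
environmental block (suitable-tree density, the two fruit indices,
rainfall) is tested against a null keeping only the human-activity
controls, the offset and any autocovariate (likelihood ratio, 4 df).

The joint spatio-temporal autocovariate uses a product of Gaussian
kernels in space (km) and time (days), self excluded; with an infinite
temporal SD it reduces exactly to the spatial autocovariate. Its two
bandwidths are selected jointly on a grid by the refit likelihood, and
the term is *retained only if significant at* $\alpha = 0.05$ under a
selection-aware parametric-bootstrap calibration
(`optimize_two_bandwidths()` repeats the full grid search on every null
replicate, so the maximisation over bandwidths is part of the null
distribution). High-leverage sites can be screened with
`leverage_screen()` (flag at $3k/n$; the multiplier is an argument).

# The synthetic landscape

`simulate_survey()` lays the three strata side by side as rectangles
with the published areas (32.45, 54.26 and 7.13 km²) and runs west–east
transects every 500 m, split into segments so per-stratum transect
counts and efforts approximate the study design (about 30 transects /
65 km in Nkala, 70 / 108 km in Mpelu, 7 km in the small stratum). Nests
are deposited by a Thomas-style cluster process — parents are nesting
sites, offspring are nests within a 15 m radius so pairwise distances
respect the 30 m same-site rule, with ~14 nests per site — with an
expected standing crop of builders × 1.37 nests/day × 183 days, and
thinned by half-normal detection (default scale 12 m) from the nearest
transect. Planar kilometre coordinates on a local projection are used
throughout (the study extent is ~17 km, so geodesy would add nothing).
Default builder numbers per community and year are 0.75 of the published
community sizes (Nkala 15/12/13, Mpelu 23/8/13).

`simulate_decay_histories()` draws disappearance ages by inverting the
logistic survival curve (defaults $\beta_0 = 4.6$,
$\beta_1 = -0.025$/day, i.e. a ~184-day mean) and emits weekly revisit
records with monotone condition codes. `simulate_phenology()` produces
biweekly per-species fruiting proportions
$\text{baseline} + A\sin(\theta + \phi) + \text{offset}\cdot[\text{Nkala}]
+ \varepsilon$, clipped to $[0,1]$ (defaults: baseline 0.3, amplitude
0.15, Nkala offset 0.1, noise SD 0.05 — a moderate, realistic seasonal
signal against observation noise). `simulate_questionnaire()` draws
person-level activity records with interview counts fixed at the
published census table and gender constraints honoured by construction.
`simulate_nesting_sites()` generates the cohesion data under either
community regime, with the fruit-at-site effect defaulting to 0.109 per
SD and an optional Gaussian spatial field for autocorrelation studies.

Every generator is a pure function of its configuration and an integer
seed; one master seed derives per-stage child streams, so the whole
pipeline (`run_pipeline()`) is reproducible end to end.

**What the generator does not emulate.** Real nest surveys have
observer-specific detection, habitat-dependent decay, irregular transect
geometry, non-rectangular home ranges that shift between years, and
species-specific phenology with masting; the generator has none of
these. Passing calibration tests on this generator therefore shows that
the estimators are correct *under their own assumptions* (half-normal
detection, logistic decay, log-linear count models), not that those
assumptions hold in any particular forest.

# Numerical choices and problem sizes

* Detection fits run on log-scale parameters with BFGS; ESW by adaptive
  quadrature at 1e-9 relative tolerance; monotonicity checked on a
  512-point grid; truncation root-finding at 1e-9.
* Ties in AIC model selection go to the fit with fewer parameters.
* Decay: closed form and quadrature cross-checked at 1e-6 relative; the
  quadrature splits the domain at the survival midpoint so near-step
  curves are resolved.
* glmmTMB fits cap optimiser iterations (500) so degenerate simulated
  datasets cannot hang; non-convergence is flagged, never silently
  accepted.
* The internal ZINB optimiser uses log-sum-exp for the zero class and is
  started from the no-autocovariate solution inside bootstrap loops.
* Calibration studies in the test suite use problem sizes chosen to make
  Monte-Carlo error small relative to the tested margins: 200 replicate
  surveys for density-CI coverage, 1000 replicates for the year-test
  size, 100 outer replicates (inner bootstrap 100) for decay coverage,
  150 seeds for seasonality recovery, 300 total for hypothesis
  selection, 50 null seeds for the calibrated autocovariate test.

# Known limitations

* The %CV composition (which variance components enter) follows the
  delta-method combination of encounter rate, detection and decay; field
  software may combine components differently, so CVs are reproducible
  in kind, not to the digit.
* The autocovariate bandwidth is weakly identified whenever unit spacing
  is much smaller than the correlation range; the studentised profile
  mitigates but cannot remove this.
* The residual-autocovariate approach absorbs autocorrelation rather
  than modelling it; CAR/SAR or kriging models are out of scope.
* The decay model is binary (present/absent); the intermediate condition
  codes are generated but not modelled.
* One-pass autocovariate construction (residuals from the no-AC model)
  is used throughout; no fixed-point iteration.
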