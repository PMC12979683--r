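---
title: "Density surface modelling of juvenile sawfish gillnet surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density surface modelling of juvenile sawfish gillnet surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sawfishDSM)
```

## The problem

Juvenile smalltooth sawfish (*Pristis pectinata*) occupy shallow,
mangrove-fringed estuarine nurseries where encounters in random surveys are
rare: a decade of monthly random gillnet sampling produces a few thousand
sets but only on the order of a hundred juvenile captures. Estimating where
the animals are, whether their relative abundance is trending, and how many
breeding females must be supplying the nursery therefore requires a model
that (i) borrows strength across space and time through environmental
covariates, (ii) handles a zero-inflated, overdispersed catch response, and
(iii) propagates parameter uncertainty into the abundance summaries.

`sawfishDSM` implements that workflow end to end and pairs it with a
synthetic estuary-and-survey generator whose ground truth is known, so every
stage can be tested as a recovery problem rather than against unavailable
field data.

## The density model

For gillnet set $i$ with catch $y_i$ (juveniles at most 1.86 m stretch total
length, STL, spanning the age-0 and age-1 classes) the model is a Tweedie
generalized additive model with a log effort offset:

$$
y_i \sim \mathrm{Tw}(\mu_i, p, \phi), \qquad
\log \mu_i = \log E_i + \beta_0 + \sum_j f_j(x_{ij}) + \text{factor terms},
$$

where $E_i$ is effort in yard-minutes (soak minutes times net area in square
yards), the $f_j$ are penalized thin-plate regression splines of the
continuous covariates (dissolved oxygen, temperature, salinity, pH, minimum
depth, mangrove focal sum, minimum mangrove distance to shore, year,
signed distance to the river mouth), and Season, River and the
developed-shoreline flag enter as parametric factors. The Tweedie power
$p \in (1,2)$ makes the response an exact compound Poisson–gamma — a point
mass at zero plus a continuous positive part — which is the natural family
for zero-inflated overdispersed catches; $p$, $\phi$ and all smoothing
parameters are chosen by REML. The reported AIC is the conditional AIC of
the penalized fit (effective-degrees-of-freedom corrected), and this
definition is recorded in every `FitResult`.

Model selection enumerates all subsets of the toggleable candidate
covariates ($2^{10} = 1024$ specifications for ten candidates), discards any
subset containing a covariate pair with $|\rho| > 0.7$ on the fitting data,
ranks the fits by AIC, and cross-validates the near-best set (within two AIC
points) to pick the member with the highest held-out AUC; ties break to
fewer covariates, then lower AIC. Which covariates are toggled versus always
included is a configuration choice (`alwaysInclude`); the pipeline default
keeps the developed-shoreline flag and year in every candidate model, year
being the carrier of the interannual trend.

## The synthetic study system

The generator is not a convenience fixture: its defaults *are* the study
conditions the analysis is designed for.

* **Scene.** A schematic rectangular estuary (default 30 × 30 cells of
  200 m, mirroring the survey's square "micro grids") with an open harbor in
  the south and three straight rivers (A, B, C) entering from the north.
  Geometry is deliberately schematic: the statistics downstream depend on
  covariate structure, not cartography. Depth shoals toward shore; mangrove
  cover is a Bernoulli raster at sub-cell resolution (20 m by default) whose
  probability decays away from the shoreline and is boosted near river
  mouths and suppressed along developed shorelines. Distance to the river
  mouth is signed, negative seaward of the mouth. Per-cell habitat
  covariates (minimum depth, mangrove focal sum `Sum_MNN`, minimum mangrove
  distance to shore `Min_MDTS`) are computed through the same raster
  toolkit the analysis exposes, so the generator exercises it.
* **Environment.** Daily temperature, dissolved oxygen, salinity and pH
  surfaces: a sinusoidal seasonal cycle, a logistic upriver freshening
  gradient for salinity, and spatially smooth random day-to-day variation
  built from four low-frequency spatial basis functions. Values are clipped
  to the observed envelopes of the study system (temperature
  14.7–35.8 °C, DO 0.4–11.9 mg/L, salinity 0.1–35.9). Fields are recomputed
  deterministically from (seed, date), so a thirteen-year series costs no
  storage.
* **Survey.** Stratified random sets per region per month (default
  6 + 5 + 5 = 16 sets across the three rivers on two trip dates each, over
  2010–2022, giving 2496 sets) in water-depth-≤ 3 m cells, with 61-m nets
  (occasionally 30.5-m) of configurable height. The field protocol fixes
  net length and mesh but not height, so net height is an explicit
  configurable defaulting to 2.5 m. Catches are exact compound
  Poisson–gamma draws with mean `effort × exp(eta)` under the known truth,
  rounded to integer fish, each fish receiving a length and sex. The default
  intercept (−11.4) was calibrated once so the expected total catch is of
  the order of one hundred juveniles over the series — the sparse-catch
  regime of the motivating survey (99 juveniles over 2543 sets) — and is
  not revisited per experiment.
* **Sightings.** Independent point–date records drawn with probability
  proportional to the true density over valid-depth cells, which gives the
  external-validation statistic a positive control (density-proportional)
  and a negative control (uniform truth).

What the generator does **not** emulate: tides, prey and predator fields,
spatial autocorrelation of catches beyond what the covariates induce,
observer error in sighting positions, and real shoreline cartography.
Passing recovery tests therefore demonstrates that the estimation machinery
is correct and calibrated under the assumed data-generating process, not
that the model is adequate for any particular real estuary.

## Habitat rasters

Mangrove classification is supervised maximum likelihood: per-class
signatures (mean and band covariance from labelled training pixels, with a
ridge of $10^{-6} \times \mathrm{trace}/\text{bands}$ added to degenerate
covariances) and per-pixel priors. In urban pixels the mangrove prior drops
to 2% with the other two classes splitting 98% equally — the standard
two-run urban/non-urban protocol is exactly equivalent to one run with this
composite prior map, and a test asserts that equivalence. Distance from
mangrove pixels to the shoreline is true point-to-segment distance within a
buffer (10 m by default, matching the tools the workflow descends from; the
synthetic scene uses a buffer scaled to its coarser pixels). The mangrove
neighbourhood statistic is a focal count over an 8 × 8 window; an even
window has no centre, so the focal cell is anchored at position (4, 4)
(0-indexed offsets −4..+3), the convention of common focal-statistics
tools, and cells off the raster count as non-mangrove, giving the range
1–64. Zonal statistics aggregate to micro-grids, with a mangrove-free grid
reported as `Sum_MNN` = 0 (no mangrove habitat) rather than missing, while
`Min_MDTS` stays missing there.

## Interpolation

The field workflow interpolates daily sonde observations with a proprietary
kriging tool; here the interpolator interface is ordinary kriging with an
exponential variogram (range defaulting to a quarter of the domain
diagonal, nugget 0 so the interpolator is exact at observations) with
inverse-distance weighting as a fallback, since the analysis needs only
smooth daily covariate surfaces. Sub-daily observations are averaged per
location per day first; a day with fewer than three points falls back to a
season-mean field with a warning.

## Validation

Internal validation is ten-fold cross-validation, stratified on
presence/absence so folds contain positives whenever possible. Each fold
reports RMSE on counts and the AUC of held-out predictions against the
binary outcome (catch > 0); because it is genuinely ambiguous whether a
median-threshold procedure means the single operating point or the full
curve, both are reported: `foldAUC` is the full-ROC (Mann–Whitney) AUC, and
`aucAtThreshold` is the single-point AUC at the training-median prediction
threshold.

External validation scores each independent sighting by the ratio of the
model prediction at its location and date to the domain-wide daily median
prediction over valid depths (0–3 m), minus one. The phrase "daily median
Z-score transformed" admits two readings; the ratio-to-median-minus-one
form is used as the default because it is the one consistent with centring
scores at zero by subtracting one and with judging consistency by the
proportion of scores above zero, and a per-day Z-scoring of predictions is
available behind `zscoreMode = "zscore"` for sensitivity analysis. The
ratio construction makes scores invariant to rescaling all predictions,
uniform sightings land at a proportion of one half by construction, and a
one-sample t-test of the mean score against zero summarizes the evidence.

## Abundance

The prediction grid clips micro-grids to the nearshore sampling frame:
within 61 m of the shoreline and at most 3 m deep (cells exactly at 3 m are
kept; the rule removes strictly deeper water). Each cell's soak area is its
clipped water area in square yards, computed by sub-cell pixel counting,
and cells that ever held a survey set form the sampled domain.

Uncertainty is propagated by posterior simulation: 1000 coefficient vectors
from the fitted model's posterior (Metropolis–Hastings on the penalized
posterior by default, with a Gaussian `N(beta, V)` approximation as an
option), each mapped to a total abundance per year and season as
$\sum_{\text{cells}} A_c \, t_{\text{ref}} \, e^{\eta_c}$ with $A_c$ the
soak area, $t_{\text{ref}}$ a reference 60-minute soak, and $\eta_c$ using
season-averaged daily environmental fields. Abundance is thus defined
operationally as the expected catch if every grid cell were swept for one
standard soak at catchability 1 (catchability is fixed at 1 and its
variance is not propagated — a stated limitation of the approach, not an
oversight). Draws exceeding 100 × the stratum median — density projections
into poorly sampled covariate space — are masked before summarizing; the
factor is configurable and `Inf` disables trimming exactly. Seasonal and
domain contrasts reuse the same draw set, so they are paired at the draw
level. Interannual differences are tested by one-way ANOVA on draw-level
totals with Tukey HSD and a compact letter display; draw-level totals (not
cell-level densities) are the analysis unit, the alternative being noted as
an open choice. Trend is summarized by successive-year ratios of medians.

## Demographic back-calculation

Two routes from juvenile abundance to adult females:

* **Brood size.** Combined age-0 + age-1 female abundance is modelled as a
  truncated normal ($\mu = 251.481$, $\sigma = 81.41511$, bounds 178.511
  and 504.7369); total juveniles are those draws divided by the female
  fraction (0.5), which is why doubling the parameters reproduces the
  juvenile summaries 503 / 357 / 1009 after rounding. The summary mode
  divides the median by the brood-size midpoint (10.5 for broods of 7–14)
  and the range endpoints by the opposite brood extremes, rounding half
  away from zero — giving 48 adult females with range 26–144 — while the
  Monte Carlo mode divides juvenile realizations by uniform brood draws
  (continuous by default; integer-valued behind a flag, since brood-size
  granularity is unstated). The biennial reproductive cycle is treated as
  already embodied in dividing the standing two-cohort abundance by a
  single brood — each female contributes one brood per two years — with no
  extra factor.
* **Stable age distribution.** Each realization draws the juvenile female
  abundance from the truncated normal and an integer maturity age uniformly
  on 7–11, then scales by (stable-age mass at ages ≥ maturity) / (mass at
  ages 0–1). The stable-age vector itself is an external input (two-column
  age/proportion), because the published vector this approach leans on is
  not printed anywhere reproducible; `syntheticStableAge()` provides a
  clearly labelled synthetic stand-in built from cumulative survivorship
  (lower survival in the first two years), which reproduces the shape and
  order of magnitude — tens of adult females — but not any particular
  published value.

## Numerical choices and degenerate inputs

* Tweedie sampling is the exact compound Poisson–gamma construction, never
  an approximation; its zero mass has the closed form
  $\exp(-\mu^{2-p}/(\phi(2-p)))$, used as a test oracle.
* Basis dimension defaults to $k = 10$ per smooth (reduced automatically
  when a covariate has fewer distinct values); observed effective degrees
  of freedom in this problem class are far below that.
* Non-converged fits are flagged and excluded from selection rather than
  propagated.
* Truncated-normal draws use inverse-CDF sampling, so bounds hold exactly.
* A non-positive-definite coefficient covariance is repaired to the nearest
  positive-definite matrix by eigenvalue clipping, with a message.
* Every stochastic operation takes an explicit seed and restores the global
  RNG state; nothing depends on ambient RNG state.
* Unknown-sex fish are aged with a configurable 1.36 m midpoint cutoff —
  an explicit package decision, not a field convention.

## Problem sizes used in the test suite

The recovery experiments run at the study's own scale where the claim
demands it — 2496 sets per replicate for selection consistency and partial
effect recovery, 20 replicates; 500 sightings per validation control — and
at reduced scale where the property is scale-free: the coverage experiment
uses four-year surveys (~960 sets) with 400 posterior draws per replicate,
and most unit tests run on a 16 × 16-cell scene with a four-year survey.
These sizes are the package's chosen test conditions and are recorded here
so they can be revisited deliberately rather than drifting.

## Known limitations

* Space enters only through covariates and river factors; there is no
  spatial random field, matching the modelling scope this package
  implements.
* The abundance scale depends on the reference soak and catchability 1;
  comparisons across years are unaffected, absolute numbers inherit those
  conventions.
* The synthetic scene's schematic geometry cannot probe failures caused by
  real coastline complexity (e.g. canal networks), which field studies
  flag as the place the model over-predicts.
* Exact reproduction of a published stable-age back-calculation requires
  the original stable-age vector, which is not shipped.

## A minimal run

```{r, eval = FALSE}
cfg <- runConfig(scene = estuaryConfig(nx = 14L, ny = 14L),
                 design = surveyDesign(years = 2010:2011),
                 candidates = c("Avg_DO", "Avg_temp"), cv = FALSE,
                 nDraws = 100L, sampler = "gaussian", seed = 7L)
res <- runPipeline(cfg, "run-demo")
res$demography$broodsize_summary
```

Every output file written by `runPipeline()` carries the configuration
hash, and a rerun with the same configuration reproduces every number
exactly; `fromStage` restarts the pipeline from a stored survey table.
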