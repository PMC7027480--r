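---
title: "Modeling old-growth structural development from climate and topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling old-growth structural development from climate and topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogdex)
```

## The model

`ogdex` treats a stand's structural state as one point on a latent
logistic development trajectory. The observable is a composite old-growth
index $I_{og} \in [0,1]$: the mean of four subindices that rescale mean
dbh, SD of dbh, live-tree density and large-tree density between a young
reference median ($x_{young}$, index 0) and an old-growth reference median
($x_{old}$, index 1), clipping values outside the reference range. Because
the rescaling is signed, tree density — which falls as stands age — needs
no special handling: its $x_{old} < x_{young}$ and the same linear map
applies.

On the logit scale the trajectory is linear in stand age:

$$\mathrm{logit}(I_{og,j}) = \beta_0 + \mathrm{coeff}_j \cdot a_j
  + u_{site(j)} + \pi_{term(j)} + e_j,$$

where $a_j$ is stand age, $u$ a Normal$(0,\sigma^2_{plot})$ random plot
intercept (plots are remeasured across survey periods), $\pi$ a fixed
effect of measurement periods 1–2 relative to period 3 (older surveys
systematically under-measured structure), and $e_j$
Normal$(0,\sigma^2_{resid})$. The development **rate** varies with the
environment:

$$\mathrm{coeff}_j = \beta_1 + \sum_{k=1}^{6}
  \left(\beta_{k,1} x_{k,j} + \beta_{k,2} x_{k,j}^2\right),$$

a quadratic in six standardized covariates — snow depth, warmth index,
slope angle, positive openness, $\log_{10}$ catchment area, and relative
solar radiation. The intercept $\beta_0$ is held constant across plots:
initial post-disturbance structure is treated as homogeneous, and all
environmental dependence is funneled through the rate. This makes the
model a varying-slope hierarchical regression that is, after expansion,
linear in 16 fixed effects (intercept, age, 6 age·$x_k$, 6 age·$x_k^2$,
2 period indicators).

### The $\varepsilon$-adjusted logit

Clipping creates exact 0s and 1s, which the logit cannot take. Exact 0s
are replaced by the smallest nonzero value observed in the response
(`eps_low`) and exact 1s by one minus the smallest nonzero complement
(`eps_high`), both capped at 0.5. The two boundaries get separate
epsilons by default because the minimum-nonzero convention is naturally
per-boundary; `epsilon_from_data(..., symmetric = TRUE)` collapses them
to a single $\varepsilon$ for the simpler reading. The rule is derived
per response — separately for $I_{og}$ and for each subindex when those
are modeled — and stored in the fit, so predictions and cross-validation
reuse exactly the transform the fit saw.

## Fitting

The expanded model is a Gaussian linear mixed model, so it is fitted with
a fully conjugate Gibbs sampler written for this package:

* fixed-effect block: joint multivariate-normal draw from its full
  conditional under Normal$(0, 10^6)$ priors;
* plot intercepts: independent normal conditionals;
* $\sigma^{-2}_{plot}, \sigma^{-2}_{resid}$: Gamma$(0.001, 0.001)$ priors,
  inverse-gamma conditional draws.

These are the conventional vague choices; the hyperparameters are exposed
in `fit_config()` and moderate changes do not move the estimates. Three
chains run from overdispersed starts (fixed effects drawn
Normal$(0, 2^2)$; chain $c$ seeded `seed + c`, so a fit is bit-reproducible
given its seed). Convergence uses the classic Gelman–Rubin
$\hat R = \sqrt{\{(n-1)W/n + B/n\}/W}$ per parameter; while any
$\hat R \ge 1.1$ the chains are extended by another full round of
iterations, up to `max_extension_rounds`, and flagged if still not
converged. The default burn-in is 1000 iterations rather than the bare
minimum of 100: a bespoke sampler earns the longer warm-up, and the
shorter setting remains available through `fit_config(burn_in = 100)`.

Covariates are standardized before the design is built (squares are taken
*after* standardizing, which is what keeps the quadratic terms stable),
and the scaler is stored in the fit so prediction and mapping reuse it.
Goodness of fit is reported as the squared Pearson correlation between the
$\varepsilon$-logit of the observed index and the fixed-effect predictor —
period effects included, plot effects excluded — and the holdout machinery
repeats random 90/10 splits by sample row, refitting and rescoring each
time. Splitting by row means repeated measurements of one plot can sit in
both halves; a plot-level split would be stricter, but row-level splitting
is the convention this machinery mirrors, and the refits recompute the
$\varepsilon$ rule per training split.

## Prediction and mapping

Spatial prediction uses posterior means (medians are nearly identical in
practice and available via `estimate = "median"`; full posterior
propagation is deliberately out of scope). For target index $q$, the age
$t_q$ solves $\beta_0 + \mathrm{coeff} \cdot t = \mathrm{logit}(q)$. The
solver brackets on $(0, 1000]$ years and uses `uniroot` at tolerance
$10^{-9}$; it must and does agree with the closed form
$(\mathrm{logit}(q)-\beta_0)/\mathrm{coeff}$ to $10^{-6}$. Three edge
cases are made explicit: a non-positive rate is *unreachable* (sentinel
value, default −1, distinct from raster nodata); a root beyond 1000 years
is likewise unreachable (no forest in the data is remotely that old, so
the extrapolation would be meaningless); and a stand already at or above
the target at age 0 returns $t = 0$. Before any cell is predicted its
covariates are clamped to the training data's 2.5–97.5% quantiles, so maps
never extrapolate beyond the fitted covariate range.

## Terrain covariates

The DEM operators are deliberately plain, deterministic implementations
of the standard definitions, each with an exact oracle used in the tests:

* **Slope** — Horn's 3×3 weighted finite differences; edge cells fall back
  to one-sided differences. An inclined plane returns $\arctan$ of its
  gradient everywhere.
* **Positive openness** — mean over azimuths (default 8, radius 200 m) of
  90° minus the maximum elevation angle to the terrain along that azimuth;
  flat ground is exactly 90°, ridges exceed it.
* **Catchment area** — depressions filled by iterative Planchon–Darboux
  relaxation with a $10^{-6}$ m epsilon gradient (so plateaus drain
  deterministically), then single-direction D8 routing with ties broken in
  the fixed order E, SE, S, SW, W, NW, N, NE; the area of a cell is
  (upslope cells + 1) × cell area, and cells with no lower in-grid
  neighbor drain off the map. The modeling pipeline uses
  $\log_{10}$(catchment area): the raw quantity is extremely right-skewed.
* **Solar radiation** — clear-sky annual potential direct insolation on
  each cell's slope/aspect (daily loop over the year, hourly steps, solar
  declination from the standard sine approximation), normalized by the
  flat-surface sum at the same latitude so flat cells are exactly 1. No
  horizon shading, no atmosphere; latitudes beyond ±66.5° are refused
  rather than mishandled.

Snow depth and warmth index are pass-through inputs (climate surfaces are
interpolated products, not DEM derivatives); `warmth_index()` computes the
thermal sum from monthly means where station data are at hand.

## The synthetic generator

The generator is the package's stand-in for restricted inventory data and
defines the conditions under which everything is tested. Its defaults are
fixed, not tuned: 500 plots × 3 periods; first-period ages lognormal with
median 50 y (the most common stand age in the data the design mirrors)
advancing 5 y per period; Gaussian-copula covariates whose latent
correlation sets snow↔warmth to −0.57 and openness↔log₁₀CA to −0.62 with
all other pairs independent; marginals chosen as plausible temperate
mountain-forest stand-ins (snow 150 ± 60 cm, warmth 100 ± 22 °C·month —
mostly inside the 45–180 screening band — slope 25 ± 8°, openness 90 ± 8°,
log₁₀CA 3 ± 0.6, radiation 1 ± 0.08). True parameters put the average-site
trajectory through index 0.5 near age 103 and ≈ 0.79 at age 150, with
period biases −0.6 and −0.3 on the logit scale and
$\sigma_{plot} = 0.6$, $\sigma_{resid} = 1.6$ — noise levels at which the
fixed effects explain a quarter to a third of the logit-scale variance,
the regime the method is meant for. Normal marginals are used for the
correlated pairs precisely so the configured latent correlation *is* the
Pearson correlation being checked.

What the generator does **not** emulate: spatial autocorrelation between
plots, the 4-km inventory lattice, non-logistic disturbance histories,
heteroscedastic measurement error, or real covariate marginals. Passing
recovery tests therefore validate the estimation machinery — that the
sampler finds the right posterior for data from this model family — not
any region-specific effect size.

`gen_tree_list()` closes the loop at the tree level (gamma dbh draws
moment-matched to a target mean/SD, truncated at 5 cm, tail-adjusted to
hit the large-tree count exactly) so the stand-metrics stage can be tested
end to end, and `gen_dem()` provides plane/valley/smooth-noise DEMs with
known analytic terrain properties.

## Numerical and design choices

* Large-tree threshold dbh ≥ 40 cm (inclusive), lower cut dbh > 5 cm
  (strict): the qualifying conventions of the structural variables;
  both configurable in `compute_stand_structure()`.
* Plot area defaults to 0.1 ha and is always an explicit argument —
  inventory plot geometry varies and densities scale by 1/area.
* Young reference stands: age ≤ 30 y (`select_young_reference()`, cutoffs
  configurable, including an optional lower bound since the status of
  stands under ~10 y is a judgment call). Reference bounds use medians —
  robust to the long tails of structural variables — with the midpoint
  convention for even-sized sets, and coinciding young/old medians are a
  hard error naming the variable (the subindex would be undefined).
* Sample SD (n−1) for the dbh spread; a single qualifying tree has SD 0,
  zero qualifying trees leave mean/SD missing with densities 0.
* Warmth screening keeps 45 ≤ WI ≤ 180 inclusive; samples with missing WI
  are dropped with a warning rather than silently.
* Chains are stored post-burn-in as one matrix per chain and persist as
  plain tab-separated text plus a JSON sidecar (seeds, priors,
  $\varepsilon$, scaler, clamp quantiles, $\hat R$) — everything needed to
  reproduce or audit a fit.

## Problem sizes

The test suite and acceptance script run the full machinery at sizes
chosen to exercise every code path while staying quick on a single CPU:
recovery experiments use 10 replicates of 1500 samples (500 plots × 3
periods) with 3 chains of 2000–3000 post-burn iterations; the map-level
inverse-consistency check uses a 100×100 cell stack; generator correlation
checks use n = 20000. These sizes are stated here as the package's own
validation design. The near-noiseless validation runs use longer chains
(burn-in 1000, 3000–4000 iterations): with the variance components pinned
at their prior floors the sampler mixes more slowly, which is a property
of the degenerate regime, not of typical data.

## Known limitations

* The logistic trajectory is a strong simplification — no disturbance
  history, no varying intercept, no spatial residual structure.
* The index weights its four subindices equally; no species composition
  or dead-wood information enters.
* Mapping propagates point estimates, not posterior uncertainty.
* The D8/openness/radiation operators are single-algorithm
  implementations with fixed conventions (documented above), not a menu
  of GIS variants.
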