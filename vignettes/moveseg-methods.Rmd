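---
title: "Models and methods behind moveseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind moveseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moveseg` chains four statistical components — a continuous-time movement
model, a hidden Markov model over interval summaries, post hoc covariate
models, and kernel space-use estimators — plus a synthetic-data generator
that makes each component verifiable by parameter recovery. This vignette
documents the models, their assumptions, the tunable parameters and their
defaults, the numerical choices, and what the tests do and do not
establish.

## Coordinate frame and units

All filtering, step and density arithmetic happens in a local planar frame:
kilometers east/north of a study centroid (default 38.5°N, 14.7°E, the
Aeolian capture region), built from geodesic distance and bearing to the
centroid (an azimuthal-equidistant construction via `geosphere`). For a
study area roughly 10³ km across, the projection distortion is orders of
magnitude below Argos location error, which is why longitudes/latitudes are
produced only by inverse projection of the results. Longitude is assumed to
stay within (−180, 180): the frame has no antimeridian wrap logic — a
documented limitation, irrelevant for Mediterranean-scale data. Timestamps
are ISO-8601 UTC in files and numeric seconds internally, so interval
arithmetic (Δt in hours) is exact. Duplicate-timestamp fixes keep the first
record; the rule is arbitrary but deterministic.

## The movement model (CTCRW)

Position is modeled as the integral of a 2-D Ornstein–Uhlenbeck velocity
process: `dv = −β v dt + σ dW`, per axis, with shared parameters. The two
parameters have physical readings: `1/β` (h) is the velocity decorrelation
time; `σ` (km·h^−3/2) scales diffusion; `σ²/(2β)` is the stationary
velocity variance. The discrete-time transition over any Δt is available in
closed form, so the exact likelihood of irregular fixes is a Kalman-filter
prediction-error decomposition over the 4-state (position, velocity) × 2
axes system.

The measurement model is bivariate normal with covariance
`R(θ) diag((kM)², (km)²) R(θ)ᵀ` from each fix's error ellipse, orientation
θ measured from the x-axis (east) as the tags report it (a from-north
convention is available). The scale factor `k` defaults to 1 — axes treated
as 1-σ extents. Several conventions circulate in the Argos literature and
no single one is canonical, so `k` is a visible, configurable setting that
the pipeline's run report always states.

Numerical choices: optimization is quasi-Newton (BFGS) on
(log β, log σ) with 5 starts on a log-spaced β ladder from 0.02 to 5 h⁻¹
and a displacement-based σ start, relative tolerance 1e-8; the initial
state pins the position at the first fix (its ellipse covariance plus 1 km²
inflation) with zero mean velocity at the stationary variance; every
innovation covariance carries a 1e-10 ridge. The regular grid (default 6 h)
anchors at the first fix time — the simplest reproducible rule — and grid
points more than 48 h from the nearest fix are flagged rather than
truncated. Imputations are joint draws of the position process by
forward-filtering backward-sampling on the merged fixes-plus-grid timeline;
the tests verify the ensemble mean and covariance against the smoother.

## Interval records and their summaries

Step length is the great-circle distance between successive 6-hr positions;
the turning angle is the signed bearing change, wrapped to (−π, π], with
the first interval's angle undefined, and angles adjacent to zero-length
steps undefined too (a zero step has no bearing). Dives are assigned to the
interval containing their start — tags report dive starts, and there is no
canonical convention for boundary-spanning dives, so a deterministic rule
was chosen. Haul-out spans are split across boundaries
proportionally. Temperature follows a two-stage summary: each 17-cut-point
profile reduces to (mean, median, SD), then the interval takes the median
of per-dive medians (and mean of means, mean of SDs); intervals without a
temperature-carrying dive stay missing — missingness is never interpolated.
A missing dive count is distinct from a zero count: zero means the tag
recorded no dives, missing means the stream was not recording (an optional
coverage table marks this). The first 24 h after release are dropped per
animal.

## The hidden Markov model

Three data streams per interval are conditionally independent given a
latent state `S_t ∈ {1..N}` (default N = 3) following a first-order Markov
chain (Γ, δ): step ~ Gamma (parameterized by mean/SD, converted exactly to
shape/scale), turning angle ~ von Mises (mean, concentration), dive count ~
Poisson. Missing stream values contribute likelihood 1, so partially
observed intervals still inform the fit; animals are independent series
restarted at δ, which is estimated as a free simplex parameter shared
across animals (the stationary-distribution alternative would couple δ to
Γ; the free version is more standard and was retained).

Fitting maximizes the forward log-likelihood directly (no EM) over
unconstrained working parameters: logs for positive quantities, the
Cartesian pair (κ cos μ, κ sin μ) for the angle parameters, and
multinomial logits against the diagonal for Γ's rows. Default 25 starts:
the first from data-driven moments (a tertile split on dive counts — the
stream that separates the states — with per-tertile step moments), the rest
log-normally perturbed. The likelihood inner loop (emission densities plus
scaled forward recursion) is compiled C++; invalid parameter regions return
a large finite penalty so line searches back off instead of aborting. Zero
step lengths, which regularization can produce, are replaced by half the
smallest positive step (the Gamma law has no mass at zero); the count of
replacements is reported.

State labels are made canonical by ascending Poisson dive rate: state 1 is
"transit" (fewest dives, empirically also the longest steps), state 3
"high-intensity diving". This identifies the otherwise label-symmetric
likelihood and is what makes Rubin pooling across imputations coherent:
`poolFits()` refuses fits whose dive-rate ordering is not ascending.

Multiple-imputation fitting follows field practice: a pilot fit with the
full multi-start on one realization, then each of the `nSims = 100`
imputations refit from the pilot's estimates (one start), pooled by Rubin's
rules on the working scale (point estimate = mean; total variance = mean
within-imputation variance + (1 + 1/M) × between). By default the
per-imputation fits skip the observed-information computation, so the
pooled object carries between-imputation variance only; passing
`hessian = TRUE` to `fitHMM()`/`mifitHMM()` adds the within component at
the cost of one numerical Hessian per imputation.

Diagnostics are one-step-ahead pseudo-residuals: the forecast CDF at each
observation (mid-P, `F(x−1) + p(x)/2`, for the discrete dive stream),
probit-transformed; lags 1–10 autocorrelations and a Shapiro–Wilk statistic
are attached, and constant streams are flagged as degenerate instead of
producing NaN. The von Mises CDF is evaluated by trapezoid integration on a
2048-point grid, ample for residual work. Model comparison uses
AIC = −2ℓ + 2k with k = 5N + N(N−1) + (N−1).

## Covariate analyses

The temperature model is softmax (multinomial logistic) regression of the
**Viterbi-decoded** state on the interval's median water temperature,
baseline transit, fitted by Newton–Raphson to a gradient ∞-norm below
1e-8. Hard labels match the way decoded states are usually analyzed; a
posterior-weighted variant was considered and not implemented — decoding
certainty is high on well-separated states, where the two coincide.
Intervals without dives carry no temperature and drop out. Complete
separation is detected two ways (diverging coefficients during iteration,
exploding standard errors at the optimum) and reported with a suggested
ridge (1e-6) fallback. The in-package Newton implementation is
cross-checked against `nnet::multinom` in the tests to 1e-6.

Distance to coast takes the bathymetry's zero-elevation crossings (cells
whose sign differs from a 4-neighbour) as the coastline and returns the
great-circle distance to the nearest such cell centre — resolution is
therefore one grid cell. The depth covariate samples the bathymetry at the
interval's smoothed position (not the dive's own maximum depth, which is a
behavioral quantity, not a habitat one). Activity budgets use closed-left
half-open bins, 10 km for coast distance and 400 m for depth by default.

## Space use

The utilization distribution is a Gaussian product-kernel density with the
bivariate normal reference bandwidth `h_j = σ_j · n_eff^{−1/6}` per axis,
where `n_eff = n (1 − ρ)/(1 + ρ)` and ρ is the mean lag-1 autocorrelation
of the coordinates. This autocorrelation inflation is a deliberate,
documented approximation to full autocorrelated KDE (AKDE): AKDE fits a
continuous-time movement model to choose and debias the bandwidth, a
methodology of its own that this package does not re-implement; the
inflation reproduces its first-order effect (tracks are not independent
points, so smooth more). Consequences: isopleth areas are comparable in
spirit but not numerically to AKDE areas, and no confidence intervals on
areas are produced. The grid extends 3 bandwidths beyond the data with
cells no larger than bandwidth/3 (at least 200 per axis); the density is
renormalized to integrate to 1, so isopleths (cells sorted by density until
the target mass, default 75%) and Bhattacharyya overlaps (Σ√(f_A f_B) ×
cell area, with bilinear regridding when lattices differ) are exact
functionals of the gridded density. The closed forms used in testing: a
circular Gaussian's 75% isopleth area is 2πσ²·ln 4, and equal-covariance
unit Gaussians d apart overlap by exp(−d²/8). Plain KDE smoothing inflates
a Gaussian's apparent variance by h², so the isopleth closed form is only
reached as n grows; the tests use n in the tens of thousands where the bias
is ~2%.

## The synthetic-data generator

The generator's defaults are the study conditions: 9 animals × 600 six-hr
intervals; transition matrix rows (0.86, 0.13, 0.01), (0.13, 0.80, 0.07),
(0.01, 0.13, 0.86); step means ± SD 8.152 ± 3.27, 6.2 ± 2.0, 5.3 ± 1.5 km;
angle means 0.01, 0.08, −0.11 rad with circular SDs 1.4, 1.85, 1.91
(converted to von Mises concentrations by inverting
A(κ) = I₁(κ)/I₀(κ) = exp(−s²/2)); dive rates 1.6, 6.54, 14.12 per 6 h; δ
the stationary distribution of Γ. Tracks are dead-reckoned in the planar
frame (heading accumulates the turning angles) and inverse-projected.
Argos corruption draws a Poisson number of fixes per interval (mean 3, a
realistic relay-tag yield; the source study reports only totals) at uniform
times, with one fix pinned at release so grids anchor there; each fix is
displaced by a bivariate normal draw from a sampled ellipse. The semi-major
axis is log-normal parameterized to hit the published median (4,637 m) and
mean (14,198 m) simultaneously — `meanlog = log(median)`,
`sdlog² = 2 log(mean/median)` — which also reproduces the published SD
(~41,400 m) to within a few percent; the published statistics do not
identify a distributional family, so log-normal is a generator choice, not
an inference. The axis ratio is fixed at 802/14,198 and orientation is
normal (87.64°, SD 30.41°) wrapped to [0, 180). Dives are placed uniformly
within their interval with state-dependent Gamma depth excess beyond the
4-m dive threshold; temperature profiles follow
base + seasonal·sin(2πt/yr) − lapse·depth + noise (defaults 19 °C, 4 °C,
0.05 °C/m, 0.3 °C — a plausible Mediterranean upper-ocean profile), clamped
to the sensor range [−5, 35] °C. Haul-outs occur only in transit intervals
— a fixture-richness assumption, not a biological claim. The island
bathymetry is radially symmetric (peak 1,000 m, slope 8 m/km, floor
−3,600 m), giving a closed-form coastline radius of 125 km for the
distance-to-coast oracles.

What the generator does **not** emulate: satellite-pass orbital timing
(fix times are uniform, not pass-clustered), ocean-current advection,
behavior-dependent fix rates (diving animals surface less), tag-side data
compression or transmission loss beyond simple missingness, and spatial
habitat preference. Passing recovery tests therefore show the estimators
are correct under the stated model, not that the model captures every
feature of real relay-tag data.

## Problem sizes and experiment design

The headline recovery experiment refits the 3-state model to 9 × 600
simulated intervals with 25 starts — the published operating point. The
multiple-imputation experiment uses 9 animals × 200 intervals with 100
imputations, a size at which the transition-matrix diagonal is still
recovered to ±0.03 while keeping the full regularize→impute→refit→pool
chain quick to run; the CTCRW recovery experiment uses 2,000 fixes. The
Monte-Carlo checks of the ellipse generator use 10⁵ draws because the
log-normal's coefficient of variation (~2.9) makes smaller-sample means
unstable. These sizes are the package's own test design choices.

## Known limitations

- The KDE approximation to AKDE (above): areas are not AKDE-comparable.
- No covariate-dependent transition probabilities; temperature is analyzed
  post hoc, matching the final model of the motivating analysis.
- No land-avoidance or haul-out-informed stopping in the movement model.
- GeoTIFF rasters are not read; bathymetry I/O is the plain-text ESRI
  ASCII grid.
- δ is shared across animals; per-animal initial distributions would add
  N−1 parameters per animal for little gain at these track lengths.
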