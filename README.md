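# moveseg

Behavioral segmentation of satellite-tracked marine animal movement.

`moveseg` implements the full analysis chain used to study the movements,
diving behavior and space use of satellite-tagged sea turtles (and similar
marine animals tracked with Argos relay tags):

1. **Track regularization.** Argos fixes are irregular in time and carry
   anisotropic location error described by an ellipse (semi-major axis *M*,
   semi-minor *m*, orientation *c*). A continuous-time correlated random
   walk (CTCRW) — position as the integral of a 2-D Ornstein–Uhlenbeck
   velocity with autocorrelation rate β (1/h) and diffusion scale σ — is
   fitted per animal by exact Kalman-filter maximum likelihood with a
   bivariate-normal measurement model built from the ellipses. The smoother
   predicts temporally regular locations at 6-hr steps, and a simulation
   smoother draws multiple imputations of the position process (default
   `nSims = 100`) so downstream inference accounts for location uncertainty.
2. **Interval summarization.** Per 6-hr interval: step length (great-circle
   distance between successive regular locations, km), turning angle
   (signed bearing change, radians), number of dives, maximum dive depth,
   dive time, haul-out seconds and two-stage temperature summaries of the
   17-cut-point dive profiles. The first 24 h after release are excluded
   (post-release stress).
3. **Hidden Markov model.** A 3-state HMM over the three data streams —
   step length ~ Gamma, turning angle ~ von Mises, dive count ~ Poisson —
   with a first-order state transition matrix Γ and initial distribution δ,
   fitted by direct maximization of the forward likelihood (25 multi-starts,
   states canonically ordered by ascending dive rate: transit,
   low-intensity diving, high-intensity diving). Per-imputation fits are
   pooled by Rubin's rules. Decoding by Viterbi and forward–backward
   probabilities, with the merged diving probability P(state 2) + P(state 3);
   one-step-ahead pseudo-residuals for model checking; AIC for model
   comparison.
4. **Covariates.** Multinomial logistic regression of the decoded state on
   the interval's median water temperature, and activity budgets binned by
   distance to coast (10-km bins) and seafloor depth (400-m bins) from a
   bathymetry raster.
5. **Space use.** Autocorrelation-aware Gaussian kernel utilization
   distributions (reference bandwidth with the effective sample size
   n·(1−ρ)/(1+ρ)), 75%-isopleth home-range areas, and pairwise
   Bhattacharyya overlap ∫√(f·g).

A first-class synthetic-data module (`simConfig()`, `simulateDataset()`)
generates complete datasets — true state sequences and tracks,
Argos-corrupted fixes with realistic error ellipses (log-normal semi-major
axis with mean 14,198 m and median 4,637 m), dives, temperature profiles,
haul-outs and an island bathymetry — with known ground truth, so every
stage is testable by parameter recovery against closed-form and
exhaustive-enumeration oracles.

## Worked example

Simulate three animals for 200 six-hr intervals from the default
configuration (the published fitted values of the nine-turtle study) and
refit the 3-state model on the generator's interval observations:

```r
library(moveseg)

cfg <- simConfig(n_animals = 3, n_intervals = 200, seed = 1)
ds  <- simulateDataset(cfg)
ds
#> simulatedDataset: 3 animals x 200 intervals of 6 h
#>    1805 Argos fixes, 3953 dives, 3953 temperature profiles, 58 haul-outs

fit <- fitHMM(ds$truth, nStates = 3, nStarts = 10, seed = 1)
fit
#> hmmFit: 3 states, 600 intervals, logLik -3878.7005  AIC 7803.401
#>                  state step_mean_km step_sd_km turn_mean_rad turn_kappa dive_rate
#>                transit        8.550      3.444        -0.071      0.969     1.475
#>   low-intensity diving        6.048      1.891         0.265      0.374     6.494
#>  high-intensity diving        5.207      1.348        -0.284      0.427    13.719

dec <- stateProbs(fit, ds$truth)
mean(dec$viterbi == ds$truth$state)
#> [1] 0.935
```

The three rows are the state-dependent distributions: transit has the
longest steps (8.55 km per 6 h), the strongest directional persistence
(concentration 0.97 around 0 rad) and the fewest dives (1.5 per 6 h);
high-intensity diving the shortest steps and most dives (13.7 per 6 h). At
600 intervals the estimates already sit close to the generating values
(8.152 / 6.2 / 5.3 km and 1.6 / 6.54 / 14.12 dives); recovery tightens at
the full 9 × 600 experiment exercised by the acceptance script. Decoding
recovers 93.5% of the true states here.

The end-to-end pipeline (regularization → summarization → multiple
imputation → pooled HMM → covariates → space use) runs from raw files or an
in-memory dataset:

```r
res <- runPipeline(ds, runConfig(nSims = 100, seed = 1), outDir = "out/")
res$pooled      # Rubin-pooled state-dependent parameters and Gamma
res$homeRanges  # 75% isopleth areas per animal (km^2)
res$overlap     # pairwise Bhattacharyya overlap matrix
```

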