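# flimphasor

Fit-free **phasor (polar plot) analysis** of NADH fluorescence lifetime
imaging (FLIM) data acquired by time-correlated single photon counting
(TCSPC), aimed at detecting pharmacological disruptions of cerebral
metabolism. The package is written for FLIM practitioners and methods
developers who want a tested, reproducible pipeline from raw photon-count
image stacks to statistical classification of metabolic state — together
with a synthetic TCSPC data generator, so every stage can be exercised and
validated without access to in vivo measurements.

## The method

Each pixel of a TCSPC acquisition holds a photon arrival-time histogram
`I(t)` over `T = 256` bins spanning the 12.5 ns period of an 80 MHz pulsed
laser. Instead of multi-exponential curve fitting, the decay is summarized
by its intensity-normalized Fourier components at the harmonic angular
frequency `ω = k · 2πf`:

    g(ω) = Σᵢ I(tᵢ) cos(ω tᵢ) / Σᵢ I(tᵢ)
    s(ω) = Σᵢ I(tᵢ) sin(ω tᵢ) / Σᵢ I(tᵢ)

with `tᵢ` the bin centers. Single-exponential decays fall on the *universal
circle* `(g − ½)² + s² = ¼` (with `s_max = 0.5` at `ωτ = 1` and `g = 1` as
`τ → 0`); multi-exponential mixtures fall inside it, at the fractionally
weighted vectorial sum of their component phasors. Because free NADH has a
much shorter lifetime than its enzyme-bound forms, metabolic disruptions
that accumulate free NADH pull the tissue phasor toward the free-NADH
position on the circle.

The pipeline implements:

- **Simulation** (`generate_decay`, `generate_scene`, `make_study`) —
  multi-exponential decays under periodic excitation (wraparound folding),
  Gaussian instrument response, early-bin TAC truncation and Poisson noise;
  paired baseline/treated acquisitions with per-animal and per-location
  biological variability.
- **Preprocessing** (`median_filter_stack`, `apply_mask`, `bin_decays`,
  `delta_intensity`) — 3×3 median filter, manual vessel masking, 3×3
  sliding-window decay binning, and a 5000-photon validity floor.
- **Phasors** (`pixel_phasor`, `phasor_image`, `calibrate`,
  `aggregate_measurement`) — per-pixel coordinates at arbitrary harmonics,
  referenced against a measured NADH standard by a single complex
  correction factor per harmonic.
- **Statistics** (`std_dev_ellipse`, `hotelling_t2`, `separability_report`)
  — standard deviational ellipses of condition clusters and two-sample
  Hotelling T² tests against baseline.
- **Classification** (`build_feature_table`, `train_classifier`,
  `kfold_cv_error`, `predict`) — LDA, KNN and naive Bayes on the 3-feature
  space `(g, s, ΔI)`, with stratified K-fold cross-validation and
  prediction of held-out seizure-like measurements.
- **Orchestration** (`run_full_analysis`, `make_fixtures`, plus a thin
  CLI at `inst/cli/flimphasor.R`).

## Worked example

```r
library(flimphasor)

study <- make_study(c("glycolysis_inhibition", "etc_inhibition"),
                    n_animals = 3, n_locations = 3, seed = 42)
measurements <- analyze_study(study, harmonics = c(1, 2))
report <- separability_report(measurements, harmonics = c(1, 2))
report[, c("condition", "harmonic", "t2", "p_value", "significant")]
#>               condition harmonic       t2  p_value significant
#> 1 glycolysis_inhibition        1 5.18e-02 9.75e-01       FALSE
#> 2        etc_inhibition        1 1.42e+03 7.16e-22        TRUE
#> 3 glycolysis_inhibition        2 5.20e-01 7.81e-01       FALSE
#> 4        etc_inhibition        2 1.34e+03 1.37e-21        TRUE
```

Electron-transport-chain blockage shifts the phasor cluster strongly toward
free NADH and is separable from baseline at both harmonics (large T², tiny
p), while glycolysis inhibition is statistically indistinguishable from
baseline — exactly the pattern the synthetic presets encode.

```r
feats <- build_feature_table(analyze_study(
  make_study(c("tca_inhibition", "etc_inhibition", "oxphos_uncoupling"),
             seed = 42), harmonics = 1))
err <- kfold_cv_error(feats, "lda", K = 5, seed = 42)
#> LDA 5-fold CV error: 0.000 (accuracy 100.0%)

model <- train_classifier(feats, "lda")
test <- analyze_study(make_study("seizure_like", seed = 43), harmonics = 1)
predict(model, test[test$condition == "seizure_like", ])
#> LDA prediction over 9 measurement(s):
#>   ETC      100.0%
#>   OXPHOS     0.0%
#>   TCA        0.0%
```

The seizure-like test measurements (an ETC-like disruption) are assigned to
the ETC class. Note that the synthetic presets are configured to be well
separated at these photon budgets, so near-perfect cross-validation is
expected here; real in vivo data are harder.

## Command line

```sh
Rscript inst/cli/flimphasor.R run --seed 7 --out my_run
Rscript inst/cli/flimphasor.R fixtures --seed 7 --out my_fixtures
```

`run` executes the full synthetic study (measurement table, separability
report, classification report, manifest); `fixtures` writes a deterministic,
checksummed set of small TIFF stacks for external tools.

See `vignettes/phasor-methods.Rmd` for the model, its assumptions, the
tunable parameters and the package's design decisions.
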