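---
title: "Phasor analysis of NADH FLIM: models, parameters and design decisions"
author: "flimphasor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor analysis of NADH FLIM: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimphasor)
```

## Scope and scientific background

NADH is the principal electron carrier of glycolysis and oxidative
metabolism, and the only one of its redox pair that fluoresces under
360 nm-equivalent excitation. Its fluorescence lifetime depends on binding
state: free NADH decays fast (sub-nanosecond), enzyme-bound forms decay
slowly (2–4 ns). Time-correlated single photon counting (TCSPC) FLIM
records, at each pixel, a histogram of photon arrival times relative to the
laser pulse; disruptions of mitochondrial metabolism change the relative
abundance of free and bound NADH and hence the shape of that histogram.

This package analyzes such data with the *phasor* transform rather than
multi-exponential curve fitting. The phasor of a decay `I(t)` at angular
frequency $\omega = k \cdot 2\pi f$ ($f$ the repetition rate, $k$ the
harmonic) is

$$g(\omega) = \frac{\sum_i I(t_i)\cos(\omega t_i)}{\sum_i I(t_i)}, \qquad
  s(\omega) = \frac{\sum_i I(t_i)\sin(\omega t_i)}{\sum_i I(t_i)},$$

computed over all bins at the bin centers $t_i = (i + \tfrac12)\,\Delta t$.
The transform is linear in the histogram: the phasor of a sum of decays is
the photon-weighted mean of their phasors. A single-exponential decay of
lifetime $\tau$ maps to $g = 1/(1+(\omega\tau)^2)$,
$s = \omega\tau/(1+(\omega\tau)^2)$, which traces the universal semicircle
$(g-\tfrac12)^2 + s^2 = \tfrac14$; a mixture maps to the
fractional-fluorescence-weighted vectorial sum of its component points and
lies inside the circle. Shifts toward the free-NADH position (short
lifetimes, right side of the circle) indicate free-NADH accumulation.

## The forward model behind the synthetic data

Because no in vivo dataset ships with the package, a forward simulator
stands in for the microscope; every downstream stage is validated against
it.

**Decay model.** Each tissue class is a `lifetime_mixture`: lifetimes
$\tau_i$ with fractional-fluorescence weights $f_i$ summing to one. Under
periodic excitation at 80 MHz the recorded window (12.5 ns) equals the pulse
period, so decay tails wrap into subsequent windows. The expected histogram
is computed analytically: each component is an exponentially modified
Gaussian (exponential decay convolved with a Gaussian instrument response of
configurable FWHM and temporal offset), whose CDF has a closed form; bin
masses are CDF differences summed over the pulse train until the geometric
tail falls below $10^{-16}$. Tests verify these masses against adaptive
numerical integration of the folded density to $10^{-9}$ relative
tolerance. Sampled mode draws independent Poisson counts per bin.

**Instrument artifacts.** The IRF default is Gaussian with 0.2 ns FWHM and
0.5 ns offset — the simplest model that exercises the calibration path.
TAC truncation zeroes the first 5 bins by default (the time-to-amplitude
converter is nonlinear at very early times), emulating hardware that
discards the earliest part of the decay.

**Condition presets.** Baseline tissue is a 4-component mixture: two fast
"free" lifetimes (0.3, 0.8 ns) and two slow "bound" lifetimes (2.0,
4.0 ns) at fractions (0.18, 0.22, 0.40, 0.20). The presets encode the
qualitative physiology: electron-transport-chain (ETC) inhibition shifts
fractional fluorescence strongly toward the free pool (+0.18 free fraction)
and raises intensity (ratio 1.40); TCA-cycle inhibition shifts moderately
(ratio 1.15); OXPHOS uncoupling shifts moderately with reduced intensity
(ratio 0.85, as uncoupling oxidizes the NADH pool); glycolysis inhibition is
configured essentially equal to baseline (+0.002 free fraction, ratio 1.0);
a seizure-like condition mimics ETC disruption. **These numbers are package
configuration, not measured values**: they were chosen once for qualitative
realism and are not fitted to any dataset.

**Biological variability.** Replicate structure follows the minimal
realistic design: 3 animals × 3 locations = 9 paired measurements per
condition. Variation is modeled as multiplicative log-normal perturbations
of fractions (renormalized, keeping them positive and summing to one) and
brightness: sdlog 0.02 per animal and 0.05 per location, plus a sdlog 0.03
per-acquisition intensity jitter on the treated stack. Location-dominated
dispersion keeps the nine points of a group approximately independent,
which the Hotelling test assumes. The default photon budget is 1000
expected photons per pixel, chosen so that after 3×3 binning every preset —
including the dimmest (OXPHOS, ratio 0.85) at a 3-sigma-low brightness
draw — still clears the 5000-photon validity floor that the acquisition
design is supposed to guarantee.

**What the simulator does not model:** optical blur, depth-dependent
scattering, motion, detector afterpulsing, spectral bleed-through from
NADPH or SR101, or spatial heterogeneity beyond the configured regions.
Passing tests therefore demonstrate correctness of the analysis chain and
its statistical behavior under the stated assumptions, not performance on
real cortical data.

## Preprocessing

The chain is fixed and ordered as acquired-data practice dictates: 3×3
median filter on each time-bin plane, manual vessel masking, 3×3
sliding-window decay binning, 5000-photon floor.

Design choices worth noting:

- *Median target.* The filter is applied to each count plane by default.
  Some phasor workflows filter the phasor images instead; that variant is
  exposed as `median_target = "phasor"` in `analyze_study()`.
- *Binning semantics.* "Binning with neighboring pixels" is implemented as
  a sliding-window neighborhood sum that preserves image dimensions (the
  convention of common TCSPC software), not block downsampling.
- *Edges.* All spatial windows replicate the border, so edge pixels are not
  photon-deflated into the validity floor.
- *The floor is a filter, not an error.* Pixels below 5000 binned photons
  are flagged invalid and excluded downstream.

## Phasor computation and calibration

Phasor sums use bin centers and run over the entire histogram including the
truncated early region; no background subtraction is performed. $\omega$ is
always derived as $k \cdot 2\pi f$; harmonic $k$ is an explicit argument
everywhere (default 1, with $k = 2$ used throughout the reports since
cluster geometry differs between harmonics while separability conclusions
should not).

Calibration follows the standard phasor-referencing construction: a
measured standard (free NADH in buffer) defines a single complex correction
factor per harmonic, $z \mapsto z \cdot z_{theory}/z_{measured}$, where
$z_{theory}$ is the vectorial-sum phasor of the standard's configured decay
model. The shipped default reference model is a fast bi-exponential (0.3
and 0.8 ns at fractions 0.8/0.2; intensity-weighted mean 0.4 ns), explicitly
a literature-informed configuration value. Both phase and modulation are
corrected; correcting phase only would be a one-line change but is not
exposed, as the modulation error from the IRF is what the reference
measurement is for. The correction is exact for the IRF (circular
convolution multiplies Fourier coefficients) and approximate for TAC
truncation; simulation tests show a residual below 0.01 in $(g, s)$ at
$10^6$ photons with a 0.5 ns offset and 5 truncated bins.

Per-measurement aggregation is the unweighted pixel mean of $g$ and $s$
over valid pixels, matching the "average over all pixels in the field of
view" convention; photon-weighted averaging can be had by aggregating the
photon-weighted phasor of the summed histogram instead, but is deliberately
not the default.

## Statistics

**Standard deviational ellipses** summarize cluster dispersion: center at
the bivariate mean, major axis along the rotation maximizing the standard
deviation of projected deviations (closed form
$\theta = \tfrac12\,\mathrm{atan2}(2C_{xy}, C_{xx}-C_{yy})$), semi-axes the
projected standard deviations with $1/(n-1)$ normalization. This is
eigen-equivalent to the principal axes of the sample covariance; the classic
geographic formulation differs only in normalization convention, which does
not affect the visual-dispersion use here. Tests pin the convention against
an eigen-decomposition oracle and check rotation equivariance. All points
coincident yields a zero-axes ellipse with a warning rather than an error.

**Separability** is the two-sample Hotelling $T^2$ with pooled covariance
and the exact F transformation, each condition against the designated
baseline group, per harmonic, at fixed $\alpha = 0.05$ with no
multiple-testing correction (one significance statement per condition is
reported, as is conventional for this design). The test is two-sample, not
paired: conditions are compared against the pooled baseline cluster. A
singular pooled covariance is an error unless an explicit
`pseudo_inverse = TRUE` requests the Moore–Penrose fallback. Under a
bivariate-normal null at the minimum group size (9 vs 9) the empirical size
is nominal (checked over 2000 replicates), and parametric p-values agree
with a 10,000-draw permutation oracle within Monte-Carlo error.

## Classification

Features are the pixel-averaged $(g, s)$ at one harmonic plus the relative
intensity change $\Delta I$; classes are TCA / ETC / OXPHOS. Glycolysis
measurements are excluded from training by the default class map since they
carry no signal distinguishable from baseline. Per-harmonic models are
trained separately; features are never concatenated across harmonics.

Unstated-by-convention hyperparameters are explicit configuration:

- **K-fold**: default $K = 5$, stratified by class, seeded; $K = n$ gives
  exact leave-one-out with a seed-free assignment. Fold assignment works on
  a canonical row ordering (class, then feature values), making the CV
  error invariant to input row order at a fixed seed.
- **KNN**: default $k = 3$ on per-feature z-scored features (scaling fitted
  on training data — required because $\Delta I$ and phasor coordinates
  differ in magnitude); vote ties break deterministically to the
  alphabetically smallest class label.
- **Priors**: empirical class frequencies for LDA and naive Bayes.
- **Naive Bayes** applies a $10^{-12}$ variance floor (with a message) so
  degenerate synthetic classes cannot produce zero-variance likelihoods.

## Numerical choices and degenerate inputs

- Histogram counts are validated nonnegative; stacks additionally
  integer-valued (tolerance $10^{-9}$).
- The phasor modulus bound $\sqrt{g^2+s^2} \le 1$ holds exactly for
  nonnegative histograms; a $10^{-9}$ tolerance absorbs floating-point
  rounding. Calibrated phasors may exceed 1 when the modulation scale is
  above one; they are not clipped.
- Empty histograms, all-masked images, empty measurement tables,
  single-class training sets and zero-photon decays raise immediate,
  specific errors rather than propagating NaN.
- Expected-mode bin masses are renormalized to sum exactly to one, so the
  expected total photon count equals the requested budget.
- All randomness flows through explicit integer seeds; scenes, studies and
  full runs are byte-reproducible given the seed.

## Problem sizes used by the test suite

The validation studies run at 16×16 pixels × 256 bins per scene with 9
paired scenes per condition — large enough that each measurement averages
~250 valid binned pixels (the phasor standard error is then dominated by
biological dispersion, as in practice), small enough that the full suite of
replicated studies stays comfortable on a single CPU. The statistical
calibration checks use 2000 null replicates (Hotelling size) and 20
datasets × 10,000 permutations (parametric-vs-permutation agreement);
analytic phasor checks use fine discretizations of 4096–8192 bins.

## Known limitations

- Presets are qualitative: absolute cluster positions and separability
  magnitudes in the synthetic study are configuration, and should not be
  read as predictions for real cortical NADH.
- Calibration corrects truncation only approximately; decays much faster
  than the truncated window would calibrate poorly.
- Vessel masks are inputs (manual masking); no automated vessel detection
  or image registration is provided.
- The Hotelling test treats the 9 points of a group as independent;
  strongly animal-dominated variance structures would call for a
  mixed-effects extension that is out of scope here.
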