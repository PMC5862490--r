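# Synthetic TCSPC data: multi-exponential decay forward model with periodic
# excitation folding, Gaussian IRF, early-bin (TAC) truncation and Poisson
# photon noise; condition presets; paired baseline/treated scenes; studies.

#' Multi-exponential lifetime mixture
#'
#' Lifetimes with fractional-fluorescence weights: `fractions[i]` is the share
#' of total emitted intensity contributed by component `i`, so the phasor of
#' the mixture is the fractionally weighted vectorial sum of the component
#' phasors.
#'
#' @param lifetimes Positive lifetimes in ns.
#' @param fractions Nonnegative weights summing to 1 (tolerance 1e-9);
#'   defaults to equal weights.
#' @return An object of class `lifetime_mixture`.
#' @export
lifetime_mixture <- function(lifetimes, fractions = NULL) {
  lifetimes <- as.numeric(lifetimes)
  if (length(lifetimes) == 0L || any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    stop("'lifetimes' must be positive and finite", call. = FALSE)
  if (is.null(fractions))
    fractions <- rep(1 / length(lifetimes), length(lifetimes))
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(lifetimes))
    stop("'lifetimes' and 'fractions' must have equal length", call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop("'fractions' must be nonnegative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must sum to 1 (tolerance 1e-9)", call. = FALSE)
  structure(list(lifetimes = lifetimes, fractions = fractions),
            class = "lifetime_mixture")
}

#' @export
print.lifetime_mixture <- function(x, ...) {
  cat("lifetime mixture:\n")
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  tau = %.3f ns  f = %.4f\n", x$lifetimes[i], x$fractions[i]))
  invisible(x)
}

#' Fractional fluorescence of the fast ("free") pool
#'
#' @param mixture A [lifetime_mixture()].
#' @param threshold Lifetimes strictly below this (ns) count as free NADH.
#' @return Sum of the fractions of sub-threshold components.
#' @export
free_fraction <- function(mixture, threshold = 1) {
  stopifnot(inherits(mixture, "lifetime_mixture"))
  sum(mixture$fractions[mixture$lifetimes < threshold])
}

#' Default calibration reference model for the NADH standard
#'
#' Free NADH in aqueous solution is well described by a fast bi-exponential
#' decay; this package ships a literature-informed configuration default
#' (0.3 ns and 0.8 ns at fractions 0.8/0.2, intensity-weighted mean 0.4 ns).
#' It is a configurable stand-in, not a measured characterization: replace it
#' with your own reference description when calibrating real data.
#'
#' @return A [lifetime_mixture()].
#' @export
nadh_reference_model <- function() {
  lifetime_mixture(c(0.3, 0.8), c(0.8, 0.2))
}

# Exponentially-modified-Gaussian CDF: exponential decay (rate 1/tau) excited
# at time mu, blurred by a Gaussian IRF of s.d. sigma. Computed in log space
# so the t << mu branch cannot overflow.
.exgauss_cdf <- function(t, tau, mu, sigma) {
  if (sigma <= 0) {
    p <- 1 - exp(-pmax(t - mu, 0) / tau)
    p[t <= mu] <- 0
    return(p)
  }
  z <- (t - mu) / sigma
  k <- sigma^2 / (2 * tau^2) - (t - mu) / tau
  stats::pnorm(z) - exp(k + stats::pnorm(z - sigma / tau, log.p = TRUE))
}

# Expected per-bin mass (summing to 1) of one folded, IRF-convolved
# exponential component under periodic excitation at the laser period.
# Contributions from all previous pulses (and the leading Gaussian edge of
# the next) are accumulated until the geometric tail falls below 1e-16.
.component_bin_mass <- function(tau, meta, irf = c(fwhm = 0, offset = 0)) {
  period <- 1 / (meta$rep_rate * 1e-9)  # pulse period, ns
  edges <- seq(0, meta$window, length.out = meta$n_bins + 1L)
  sigma <- irf[["fwhm"]] / (2 * sqrt(2 * log(2)))
  mass <- numeric(meta$n_bins)
  m <- -1L
  repeat {
    inc <- diff(.exgauss_cdf(edges + m * period, tau, irf[["offset"]], sigma))
    inc[inc < 0] <- 0  # guard against tiny cancellation noise
    mass <- mass + inc
    if (m >= 1L && sum(inc) < 1e-16) break
    if (m > 5000L) break
    m <- m + 1L
  }
  mass / sum(mass)
}

.mixture_bin_mass <- function(mixture, meta, irf = c(fwhm = 0, offset = 0)) {
  mass <- numeric(meta$n_bins)
  for (i in seq_along(mixture$lifetimes))
    mass <- mass + mixture$fractions[i] *
      .component_bin_mass(mixture$lifetimes[i], meta, irf)
  mass
}

#' Simulate one TCSPC decay histogram
#'
#' Forward model for a multi-exponential mixture under periodic pulsed
#' excitation: each component decay is folded modulo the laser period
#' (wraparound from previous pulses is non-negligible for ns lifetimes at
#' 80 MHz), convolved with a Gaussian instrument response of the given FWHM
#' and temporal offset, and integrated analytically over each histogram bin.
#' In `"expected"` mode the noise-free expected histogram is returned, with
#' total expected counts exactly `n_photons`; in `"sampled"` mode each bin is
#' an independent Poisson draw with that expectation (uses the current RNG
#' state; seed with [set.seed()] for reproducibility).
#'
#' @param mixture A [lifetime_mixture()].
#' @param n_photons Nonnegative expected total photon count.
#' @param meta An [acq_meta()].
#' @param irf Named numeric `c(fwhm =, offset =)` in ns; `fwhm = 0` disables
#'   the Gaussian blur.
#' @param mode `"expected"` or `"sampled"`.
#' @return A [decay_histogram()].
#' @examples
#' d <- generate_decay(lifetime_mixture(2.0), 1e6, mode = "expected")
#' pixel_phasor(d, harmonic = 1)
#' @export
generate_decay <- function(mixture, n_photons, meta = acq_meta(),
                           irf = c(fwhm = 0, offset = 0),
                           mode = c("expected", "sampled")) {
  stopifnot(inherits(mixture, "lifetime_mixture"))
  mode <- match.arg(mode)
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 0)
    stop("'n_photons' must be a single nonnegative count", call. = FALSE)
  lambda <- n_photons * .mixture_bin_mass(mixture, meta, irf)
  counts <- if (mode == "expected") lambda else stats::rpois(length(lambda), lambda)
  decay_histogram(counts, meta)
}

#' Zero the earliest histogram bins (TAC truncation)
#'
#' Emulates time-to-amplitude-converter nonlinearity at very early times,
#' which makes TCSPC hardware truncate the first part of the recorded decay.
#'
#' @param decay A [decay_histogram()].
#' @param n_trunc Number of leading bins to zero; must be `< n_bins`.
#' @return A [decay_histogram()] with bins `1..n_trunc` set to zero.
#' @export
apply_tac_truncation <- function(decay, n_trunc) {
  stopifnot(inherits(decay, "decay_histogram"))
  n_trunc <- as.integer(n_trunc)
  if (is.na(n_trunc) || n_trunc < 0L || n_trunc >= decay$meta$n_bins)
    stop("'n_trunc' must satisfy 0 <= n_trunc < n_bins", call. = FALSE)
  if (n_trunc > 0L) decay$counts[seq_len(n_trunc)] <- 0
  decay
}

# ---- condition presets -------------------------------------------------------

#' Pharmacological condition preset
#'
#' @param name Condition label.
#' @param mixture [lifetime_mixture()] of the treated tissue.
#' @param intensity_ratio Treated/baseline brightness ratio.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, mixture, intensity_ratio = 1) {
  stopifnot(inherits(mixture, "lifetime_mixture"))
  if (!is.numeric(intensity_ratio) || intensity_ratio <= 0)
    stop("'intensity_ratio' must be positive", call. = FALSE)
  structure(list(name = as.character(name), mixture = mixture,
                 intensity_ratio = as.numeric(intensity_ratio)),
            class = "condition_preset")
}

#' Default condition presets for the synthetic study
#'
#' Qualitative emulations of pharmacological disruptions of cortical NADH
#' metabolism. Baseline tissue is a 4-component mixture (two fast "free"
#' NADH lifetimes, two slow enzyme-bound lifetimes). Mitochondrial
#' disruptions (TCA-cycle inhibition, electron-transport-chain inhibition,
#' uncoupling of oxidative phosphorylation) shift fractional fluorescence
#' toward the free pool -- most strongly for ETC blockage, which also raises
#' intensity markedly -- while glycolysis inhibition is configured to be
#' essentially indistinguishable from baseline. All numeric values are
#' package configuration chosen for realism; they are not fitted to any
#' measured dataset.
#'
#' @param names Optional subset of preset names to return.
#' @return Named list of [condition_preset()]s: `baseline`,
#'   `glycolysis_inhibition`, `tca_inhibition`, `etc_inhibition`,
#'   `oxphos_uncoupling`, `seizure_like`.
#' @export
default_presets <- function(names = NULL) {
  taus <- c(0.3, 0.8, 2.0, 4.0)
  p <- list(
    baseline = condition_preset(
      "baseline", lifetime_mixture(taus, c(0.18, 0.22, 0.40, 0.20)), 1.00),
    glycolysis_inhibition = condition_preset(
      "glycolysis_inhibition",
      lifetime_mixture(taus, c(0.181, 0.221, 0.399, 0.199)), 1.00),
    tca_inhibition = condition_preset(
      "tca_inhibition", lifetime_mixture(taus, c(0.24, 0.25, 0.35, 0.16)), 1.15),
    etc_inhibition = condition_preset(
      "etc_inhibition", lifetime_mixture(taus, c(0.30, 0.28, 0.28, 0.14)), 1.40),
    oxphos_uncoupling = condition_preset(
      "oxphos_uncoupling", lifetime_mixture(taus, c(0.27, 0.26, 0.31, 0.16)), 0.85),
    seizure_like = condition_preset(
      "seizure_like", lifetime_mixture(taus, c(0.29, 0.27, 0.29, 0.15)), 1.35)
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(p))
    if (length(missing))
      stop("unknown preset(s): ", paste(missing, collapse = ", "), call. = FALSE)
    p <- p[names]
  }
  p
}

# ---- scenes ------------------------------------------------------------------

#' Specification of one paired baseline/treated synthetic acquisition
#'
#' @param height,width Pixel grid dimensions.
#' @param regions Named list; each element is `list(pixels =, mixture =,`
#'   `brightness =)` with `pixels` an integer vector of linear pixel indices
#'   (column-major into the `height x width` grid) or `NULL` for "all
#'   remaining non-vessel pixels", `mixture` a [lifetime_mixture()] and
#'   `brightness` the expected photons per pixel.
#' @param vessel_mask A [pixel_mask()] of pixels to treat as blood vessel, or
#'   `NULL` for none.
#' @param irf Named numeric `c(fwhm =, offset =)` in ns.
#' @param tac_truncated_bins Leading bins zeroed by the TAC; `< n_bins / 4`.
#' @param photon_budget_scale Global multiplier on all brightnesses.
#' @param treated_overrides Named list (same labels as `regions`) of
#'   `list(mixture =, brightness =)` replacements for the treated acquisition;
#'   omitted fields inherit the baseline value.
#' @param seed Integer RNG seed making the scene reproducible.
#' @param meta An [acq_meta()].
#' @return An object of class `scene_spec`; region pixel sets must partition
#'   the non-vessel field.
#' @export
scene_spec <- function(height, width, regions, vessel_mask = NULL,
                       irf = c(fwhm = 0.2, offset = 0.5),
                       tac_truncated_bins = 5L, photon_budget_scale = 1,
                       treated_overrides = list(), seed = 1L,
                       meta = acq_meta()) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 1L, width >= 1L, inherits(meta, "acq_meta"))
  tac_truncated_bins <- as.integer(tac_truncated_bins)
  if (tac_truncated_bins < 0L || tac_truncated_bins >= meta$n_bins / 4)
    stop("'tac_truncated_bins' must satisfy 0 <= n < n_bins/4", call. = FALSE)
  if (is.null(vessel_mask))
    vessel_mask <- pixel_mask(matrix(FALSE, height, width), "vessel")
  stopifnot(inherits(vessel_mask, "pixel_mask"))
  if (!identical(dim(vessel_mask$include), c(height, width)))
    stop("vessel mask shape does not match scene", call. = FALSE)
  if (!is.list(regions) || length(regions) == 0L || is.null(names(regions)))
    stop("'regions' must be a non-empty named list", call. = FALSE)
  tissue <- which(!vessel_mask$include)
  assigned <- integer(0)
  open <- NULL
  for (lab in names(regions)) {
    r <- regions[[lab]]
    stopifnot(inherits(r$mixture, "lifetime_mixture"))
    if (!is.numeric(r$brightness) || r$brightness <= 0)
      stop(sprintf("region '%s': brightness must be positive", lab), call. = FALSE)
    if (is.null(r$pixels)) {
      if (!is.null(open))
        stop("only one region may leave 'pixels' NULL", call. = FALSE)
      open <- lab
    } else {
      px <- as.integer(r$pixels)
      if (any(!(px %in% tissue)))
        stop(sprintf("region '%s' claims vessel or out-of-range pixels", lab),
             call. = FALSE)
      if (any(px %in% assigned))
        stop("region pixel sets overlap", call. = FALSE)
      assigned <- c(assigned, px)
    }
  }
  if (!is.null(open)) {
    regions[[open]]$pixels <- setdiff(tissue, assigned)
  } else if (length(assigned) != length(tissue)) {
    stop("region pixel sets must partition the non-vessel field", call. = FALSE)
  }
  for (lab in names(treated_overrides)) {
    if (!(lab %in% names(regions)))
      stop(sprintf("treated override for unknown region '%s'", lab), call. = FALSE)
  }
  structure(
    list(height = height, width = width, regions = regions,
         vessel_mask = vessel_mask, irf = irf,
         tac_truncated_bins = tac_truncated_bins,
         photon_budget_scale = photon_budget_scale,
         treated_overrides = treated_overrides,
         seed = as.integer(seed), meta = meta),
    class = "scene_spec"
  )
}

#' Convenience scene for one condition preset
#'
#' Single "tissue" region covering the non-vessel field, with a vertical
#' vessel band, baseline brightness and mixture from `baseline`, and treated
#' overrides from `preset`.
#'
#' @param preset A [condition_preset()] (the treated condition).
#' @param baseline A [condition_preset()] describing the pre-treatment tissue.
#' @param height,width Pixel grid dimensions.
#' @param brightness Expected photons per pixel at baseline.
#' @param vessel_frac Fraction of columns occupied by the vessel band
#'   (0 disables it).
#' @param seed,irf,tac_truncated_bins,meta See [scene_spec()].
#' @return A [scene_spec()].
#' @export
default_scene_spec <- function(preset, baseline = default_presets()$baseline,
                               height = 32L, width = 32L, brightness = 1000,
                               vessel_frac = 0.06,
                               irf = c(fwhm = 0.2, offset = 0.5),
                               tac_truncated_bins = 5L, seed = 1L,
                               meta = acq_meta()) {
  stopifnot(inherits(preset, "condition_preset"),
            inherits(baseline, "condition_preset"))
  vm <- matrix(FALSE, height, width)
  nv <- floor(vessel_frac * width)
  if (nv >= 1) {
    c0 <- max(1L, floor(width / 3))
    vm[, c0:min(width, c0 + nv - 1L)] <- TRUE
  }
  scene_spec(
    height, width,
    regions = list(tissue = list(pixels = NULL, mixture = baseline$mixture,
                                 brightness = brightness)),
    vessel_mask = pixel_mask(vm, "vessel"),
    irf = irf, tac_truncated_bins = tac_truncated_bins,
    treated_overrides = list(tissue = list(
      mixture = preset$mixture,
      brightness = brightness * preset$intensity_ratio)),
    seed = seed, meta = meta
  )
}

.sample_stack <- function(spec, treated) {
  H <- spec$height; W <- spec$width; T <- spec$meta$n_bins
  arr <- array(0, c(H, W, T))
  npix_total <- H * W
  flat <- matrix(0, npix_total, T)
  for (lab in names(spec$regions)) {
    r <- spec$regions[[lab]]
    mixture <- r$mixture; brightness <- r$brightness
    if (treated && lab %in% names(spec$treated_overrides)) {
      ov <- spec$treated_overrides[[lab]]
      if (!is.null(ov$mixture)) mixture <- ov$mixture
      if (!is.null(ov$brightness)) brightness <- ov$brightness
    }
    lambda <- brightness * spec$photon_budget_scale *
      .mixture_bin_mass(mixture, spec$meta, spec$irf)
    if (spec$tac_truncated_bins > 0L)
      lambda[seq_len(spec$tac_truncated_bins)] <- 0
    px <- r$pixels
    flat[px, ] <- matrix(
      stats::rpois(length(px) * T, rep(lambda, each = length(px))),
      length(px), T)
  }
  vessel <- which(spec$vessel_mask$include)
  if (length(vessel)) {
    # vessels are dark: low-brightness lumen signal with the first region's mixture
    r1 <- spec$regions[[1]]
    lambda <- 0.1 * r1$brightness * spec$photon_budget_scale *
      .mixture_bin_mass(r1$mixture, spec$meta, spec$irf)
    if (spec$tac_truncated_bins > 0L)
      lambda[seq_len(spec$tac_truncated_bins)] <- 0
    flat[vessel, ] <- matrix(
      stats::rpois(length(vessel) * T, rep(lambda, each = length(vessel))),
      length(vessel), T)
  }
  arr[] <- flat
  tcspc_image(arr, spec$meta)
}

#' Generate one paired baseline/treated acquisition
#'
#' Per-pixel decays are independent Poisson realizations of the region's
#' expected folded/IRF-convolved/truncated decay at the region's brightness.
#' The treated stack applies the spec's `treated_overrides`. Deterministic
#' given `spec$seed` (the global RNG is seeded and advanced).
#'
#' @param spec A [scene_spec()].
#' @return List with elements `baseline` and `treated` ([tcspc_image()]s
#'   sharing geometry and vessel mask), `masks` (vessel mask plus one
#'   [pixel_mask()] per region) and `truth` (per-region mixtures and
#'   brightnesses actually used).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  baseline <- .sample_stack(spec, treated = FALSE)
  treated <- .sample_stack(spec, treated = TRUE)
  masks <- list(vessel = spec$vessel_mask)
  for (lab in names(spec$regions)) {
    inc <- matrix(FALSE, spec$height, spec$width)
    inc[spec$regions[[lab]]$pixels] <- TRUE
    masks[[lab]] <- pixel_mask(inc, lab)
  }
  truth <- lapply(names(spec$regions), function(lab) {
    r <- spec$regions[[lab]]
    tr <- list(mixture = r$mixture, brightness = r$brightness)
    if (lab %in% names(spec$treated_overrides)) {
      ov <- spec$treated_overrides[[lab]]
      if (!is.null(ov$mixture)) tr$mixture <- ov$mixture
      if (!is.null(ov$brightness)) tr$brightness <- ov$brightness
    }
    list(region = lab,
         baseline = list(mixture = r$mixture, brightness = r$brightness),
         treated = tr)
  })
  names(truth) <- names(spec$regions)
  list(baseline = baseline, treated = treated, masks = masks,
       truth = truth, seed = spec$seed)
}

# Multiplicative log-normal perturbation of mixture fractions, renormalized.
.perturb_mixture <- function(mixture, multipliers) {
  f <- mixture$fractions * multipliers
  lifetime_mixture(mixture$lifetimes, f / sum(f))
}

#' Generate a multi-animal, multi-location synthetic study
#'
#' For each condition preset, `n_animals * n_locations` paired
#' baseline/treated scenes are generated. Biological variation is modeled as
#' multiplicative log-normal perturbations of the mixture fractions
#' (renormalized, so they stay positive and sum to one) and of brightness:
#' one draw per animal (`dispersion_animal`) and one per location
#' (`dispersion_location`), shared between the baseline and treated
#' acquisitions of a pair so that paired contrasts reflect the treatment. An
#' additional per-acquisition intensity jitter (`intensity_jitter`, sdlog) on
#' the treated brightness models physiological drift between the paired
#' acquisitions.
#'
#' @param presets List of [condition_preset()]s, or preset names understood by
#'   [default_presets()].
#' @param n_animals,n_locations Replicate counts (both `>= 1`); the defaults
#'   give the 3 x 3 = 9 measurements-per-condition design.
#' @param height,width,brightness,vessel_frac,irf,tac_truncated_bins,meta
#'   Scene geometry, see [default_scene_spec()].
#' @param dispersion_animal,dispersion_location sdlog of the between-animal
#'   and between-location log-normal effects (0 disables them).
#' @param intensity_jitter sdlog of the per-acquisition treated-brightness
#'   jitter.
#' @param baseline_preset [condition_preset()] describing pre-treatment tissue.
#' @param seed Integer seed; the study (including all scene seeds) is
#'   deterministic given it.
#' @return An object of class `flim_study`: list with `measurements` (one
#'   record per pair: `condition`, `animal_id`, `location_id`, `scene`,
#'   `truth`) and `params`.
#' @export
make_study <- function(presets, n_animals = 3L, n_locations = 3L,
                       height = 16L, width = 16L, brightness = 1000,
                       vessel_frac = 0.06,
                       dispersion_animal = 0.02, dispersion_location = 0.05,
                       intensity_jitter = 0.03,
                       irf = c(fwhm = 0.2, offset = 0.5),
                       tac_truncated_bins = 5L,
                       baseline_preset = default_presets()$baseline,
                       meta = acq_meta(), seed = 1L) {
  if (is.character(presets)) presets <- default_presets(presets)
  if (inherits(presets, "condition_preset")) presets <- list(presets)
  if (length(presets) == 0L) stop("empty preset list", call. = FALSE)
  n_animals <- as.integer(n_animals); n_locations <- as.integer(n_locations)
  stopifnot(n_animals >= 1L, n_locations >= 1L)
  set.seed(seed)
  nc <- length(baseline_preset$mixture$fractions)
  records <- list()
  for (preset in presets) {
    stopifnot(inherits(preset, "condition_preset"))
    if (length(preset$mixture$fractions) != nc)
      stop("all presets must share the baseline's component count", call. = FALSE)
    for (a in seq_len(n_animals)) {
      mult_a <- stats::rlnorm(nc, 0, dispersion_animal)
      bright_a <- stats::rlnorm(1, 0, dispersion_animal)
      for (l in seq_len(n_locations)) {
        mult <- mult_a * stats::rlnorm(nc, 0, dispersion_location)
        bright <- bright_a * stats::rlnorm(1, 0, dispersion_location)
        jit <- stats::rlnorm(1, 0, intensity_jitter)
        base_mix <- .perturb_mixture(baseline_preset$mixture, mult)
        treat_mix <- .perturb_mixture(preset$mixture, mult)
        b0 <- brightness * bright
        scene_seed <- sample.int(2147483646L, 1L)
        spec <- scene_spec(
          height, width,
          regions = list(tissue = list(pixels = NULL, mixture = base_mix,
                                       brightness = b0)),
          vessel_mask = .vessel_band(height, width, vessel_frac),
          irf = irf, tac_truncated_bins = tac_truncated_bins,
          treated_overrides = list(tissue = list(
            mixture = treat_mix,
            brightness = b0 * preset$intensity_ratio * jit)),
          seed = scene_seed, meta = meta)
        records[[length(records) + 1L]] <- list(
          condition = preset$name,
          animal_id = sprintf("%s_a%d", preset$name, a),
          location_id = sprintf("loc%d", l),
          scene = generate_scene(spec),
          truth = list(baseline_mixture = base_mix, treated_mixture = treat_mix,
                       brightness = b0,
                       intensity_ratio = preset$intensity_ratio * jit))
      }
    }
  }
  structure(
    list(measurements = records,
         params = list(n_animals = n_animals, n_locations = n_locations,
                       height = height, width = width, brightness = brightness,
                       vessel_frac = vessel_frac,
                       dispersion_animal = dispersion_animal,
                       dispersion_location = dispersion_location,
                       intensity_jitter = intensity_jitter, irf = irf,
                       tac_truncated_bins = tac_truncated_bins,
                       meta = meta, seed = seed,
                       conditions = vapply(presets, `[[`, "", "name"))),
    class = "flim_study"
  )
}

.vessel_band <- function(height, width, vessel_frac) {
  vm <- matrix(FALSE, height, width)
  nv <- floor(vessel_frac * width)
  if (nv >= 1) {
    c0 <- max(1L, floor(width / 3))
    vm[, c0:min(width, c0 + nv - 1L)] <- TRUE
  }
  pixel_mask(vm, "vessel")
}

#' @export
print.flim_study <- function(x, ...) {
  cat(sprintf("synthetic FLIM study: %d paired measurements (%s), %d x %d px\n",
              length(x$measurements),
              paste(unique(x$params$conditions), collapse = ", "),
              x$params$height, x$params$width))
  invisible(x)
}
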