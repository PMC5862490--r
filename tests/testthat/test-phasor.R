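test_that("pixel phasor handles canonical special cases", {
  m <- acq_meta(n_bins = 256L)
  # all counts in the first bin: t0 = dt/2, so (g, s) ~ (cos wt0, sin wt0) ~ (1, 0)
  c0 <- numeric(256); c0[1] <- 1000
  p <- pixel_phasor(decay_histogram(c0, m), 1)
  t0 <- bin_width(m) / 2
  om <- angular_frequency(m, 1)
  expect_equal(p$g, cos(om * t0), tolerance = 1e-12)
  expect_equal(p$s, sin(om * t0), tolerance = 1e-12)

  # uniform histogram over a full period: orthogonality gives (0, 0)
  u <- pixel_phasor(decay_histogram(rep(5, 256), m), 1)
  expect_lt(abs(u$g), 1e-12)
  expect_lt(abs(u$s), 1e-12)

  expect_error(pixel_phasor(decay_histogram(numeric(256), m)), "empty")
})

test_that("fine discretization reproduces the closed form at wt = 1", {
  m <- acq_meta(n_bins = 4096L)
  om <- angular_frequency(m, 1)
  tau <- 1 / om  # wt = 1
  d <- generate_decay(lifetime_mixture(tau), 1e6, m, mode = "expected")
  p <- pixel_phasor(d, 1)
  expect_equal(p$g, 0.5, tolerance = 1e-3)
  expect_equal(p$s, 0.5, tolerance = 1e-3)
})

test_that("phasor images agree with per-pixel calls and uniform stacks are constant", {
  m <- acq_meta(n_bins = 32L)
  set.seed(14)
  arr <- array(rpois(6 * 6 * 32, 20), c(6, 6, 32))
  img <- tcspc_image(arr, m)
  pim <- phasor_image(img, harmonic = 1)
  for (k in 1:10) {
    i <- sample(6, 1); j <- sample(6, 1)
    pp <- pixel_phasor(decay_histogram(arr[i, j, ], m), 1)
    expect_equal(pim$g[i, j], pp$g, tolerance = 1e-12)
    expect_equal(pim$s[i, j], pp$s, tolerance = 1e-12)
  }
  dec <- generate_decay(lifetime_mixture(1.5), 500, m, mode = "sampled")
  unif <- tcspc_image(array(rep(dec$counts, each = 9), c(3, 3, 32)), m)
  up <- phasor_image(unif, harmonic = 1)
  expect_equal(max(up$g) - min(up$g), 0, tolerance = 1e-12)
  expect_error(phasor_image(tcspc_image(array(0L, c(2, 2, 32)), m)),
               "no valid pixels")
})

test_that("single-exponential phasors sit on the universal circle for all tau", {
  om <- angular_frequency(acq_meta(), 1)
  expect_equal(single_exp_phasor(1 / om, om), list(g = 0.5, s = 0.5))
  expect_equal(single_exp_phasor(0, om), list(g = 1, s = 0))
  far <- single_exp_phasor(1e9, om)
  expect_lt(far$g, 1e-10); expect_lt(far$s, 1e-4)
  taus <- seq(0, 20, by = 0.25)
  p <- single_exp_phasor(taus, om)
  expect_equal((p$g - 0.5)^2 + p$s^2, rep(0.25, length(taus)), tolerance = 1e-12)
  expect_error(single_exp_phasor(-1, om), "nonnegative")
})

test_that("mixture phasors are the fractionally weighted vectorial sum", {
  om <- angular_frequency(acq_meta(), 1)
  one <- mixture_phasor(lifetime_mixture(2.5), om)
  expect_equal(one, single_exp_phasor(2.5, om))
  dup <- mixture_phasor(lifetime_mixture(c(2.5, 2.5), c(0.5, 0.5)), om)
  expect_equal(dup, one, tolerance = 1e-12)

  # 4-component mixture vs the expected-mode histogram at fine discretization
  mx <- default_presets()$baseline$mixture
  m <- acq_meta(n_bins = 8192L)
  d <- generate_decay(mx, 1e6, m, mode = "expected")
  p <- pixel_phasor(d, 1)
  v <- mixture_phasor(mx, angular_frequency(m, 1))
  expect_equal(p$g, v$g, tolerance = 1e-3)
  expect_equal(p$s, v$s, tolerance = 1e-3)
})

test_that("mixture phasors move toward the shorter component as its weight grows", {
  om <- angular_frequency(acq_meta(), 1)
  short <- single_exp_phasor(0.4, om)
  prev <- Inf
  for (f in seq(0.1, 0.9, by = 0.1)) {
    p <- mixture_phasor(lifetime_mixture(c(0.4, 3.0), c(f, 1 - f)), om)
    dist <- sqrt((p$g - short$g)^2 + (p$s - short$s)^2)
    expect_lt(dist, prev)
    prev <- dist
  }
})

test_that("phasor linearity and the modulus bound hold on random histograms", {
  m <- acq_meta(n_bins = 64L)
  set.seed(99)
  for (i in 1:50) {
    c1 <- runif(64, 0, 100); c2 <- runif(64, 0, 100)
    p1 <- pixel_phasor(decay_histogram(c1, m), 1)
    p2 <- pixel_phasor(decay_histogram(c2, m), 1)
    ps <- pixel_phasor(decay_histogram(c1 + c2, m), 1)
    w <- sum(c1) / (sum(c1) + sum(c2))
    expect_equal(ps$g, w * p1$g + (1 - w) * p2$g, tolerance = 1e-12)
    expect_equal(ps$s, w * p1$s + (1 - w) * p2$s, tolerance = 1e-12)
    expect_lte(sqrt(p1$g^2 + p1$s^2), 1 + 1e-9)
  }
})

test_that("second-harmonic phasors of single-exponential decays stay on the circle", {
  m <- acq_meta()
  d <- generate_decay(lifetime_mixture(1.8), 1e6, m, mode = "expected")
  for (k in 1:2) {
    p <- pixel_phasor(d, k)
    expect_equal((p$g - 0.5)^2 + p$s^2, 0.25, tolerance = 5e-3)
    cf <- oracle_single_exp(1.8, angular_frequency(m, k))
    expect_equal(p$g, unname(cf["g"]), tolerance = 1e-3)
    expect_equal(p$s, unname(cf["s"]), tolerance = 1e-3)
  }
})

test_that("calibration maps the measured reference onto its model phasor", {
  m <- acq_meta()
  model <- nadh_reference_model()
  th <- mixture_phasor(model, angular_frequency(m, 1))
  ident <- calibrate(phasor_point(th$g, th$s, 1L), model, m)
  expect_equal(ident$phase_shift, 0, tolerance = 1e-12)
  expect_equal(ident$modulation_scale, 1, tolerance = 1e-12)

  meas <- phasor_point(0.8, 0.1, 1L)
  tr <- calibrate(meas, model, m)
  back <- apply_calibration(meas, tr)
  expect_equal(back$g, th$g, tolerance = 1e-12)
  expect_equal(back$s, th$s, tolerance = 1e-12)
  expect_error(calibrate(phasor_point(0, 0, 1L), model, m), "zero modulus")
})

test_that("applying calibration is complex multiplication per pixel", {
  m <- acq_meta(n_bins = 32L)
  set.seed(31)
  img <- tcspc_image(array(rpois(4 * 4 * 32, 30), c(4, 4, 32)), m)
  pim <- phasor_image(img, harmonic = 1)
  ident <- structure(list(phase_shift = 0, modulation_scale = 1, harmonic = 1L),
                     class = "calibration_transform")
  same <- apply_calibration(pim, ident)
  expect_equal(same$g, pim$g); expect_equal(same$s, pim$s)
  expect_true(same$calibrated)

  rot <- structure(list(phase_shift = 0.3, modulation_scale = 1, harmonic = 1L),
                   class = "calibration_transform")
  rr <- apply_calibration(pim, rot)
  expect_equal(sqrt(rr$g^2 + rr$s^2), sqrt(pim$g^2 + pim$s^2), tolerance = 1e-12)

  tr <- structure(list(phase_shift = -0.2, modulation_scale = 1.1, harmonic = 1L),
                  class = "calibration_transform")
  out <- apply_calibration(pim, tr)
  z <- complex(real = pim$g[2, 2], imaginary = pim$s[2, 2]) *
    complex(modulus = 1.1, argument = -0.2)
  expect_equal(out$g[2, 2], Re(z), tolerance = 1e-12)
  expect_equal(out$s[2, 2], Im(z), tolerance = 1e-12)

  wrong <- structure(list(phase_shift = 0, modulation_scale = 1, harmonic = 2L),
                     class = "calibration_transform")
  expect_error(apply_calibration(pim, wrong), "harmonic mismatch")
})

test_that("simulated calibration corrects IRF and truncation distortions", {
  m <- acq_meta()
  irf <- c(fwhm = 0.2, offset = 0.5)
  model <- nadh_reference_model()
  set.seed(55)
  ref <- apply_tac_truncation(generate_decay(model, 1e6, m, irf, "sampled"), 5)
  tr <- calibrate(pixel_phasor(ref, 1), model, m, 1)
  smp <- apply_tac_truncation(generate_decay(lifetime_mixture(2.2), 1e6, m, irf,
                                             "sampled"), 5)
  cal <- apply_calibration(pixel_phasor(smp, 1), tr)
  cf <- oracle_single_exp(2.2, angular_frequency(m, 1))
  expect_lt(abs(cal$g - cf["g"]), 0.01)
  expect_lt(abs(cal$s - cf["s"]), 0.01)
})

test_that("aggregation is the unweighted pixel mean of valid phasors", {
  m <- acq_meta(n_bins = 32L)
  set.seed(61)
  img <- tcspc_image(array(rpois(5 * 5 * 32, 25), c(5, 5, 32)), m)
  pim <- phasor_image(img, harmonic = 1)
  mp <- aggregate_measurement(pim, 0.1, "cond")
  expect_equal(unname(mp$phasors[["1"]]["g"]), mean(pim$g), tolerance = 1e-12)
  expect_equal(unname(mp$phasors[["1"]]["s"]), mean(pim$s), tolerance = 1e-12)

  vm <- matrix(FALSE, 5, 5); vm[2, 3] <- TRUE
  one <- aggregate_measurement(pim, 0, "cond", valid = pixel_mask(vm))
  expect_equal(unname(one$phasors[["1"]]["g"]), pim$g[2, 3])
  expect_equal(one$n_valid_pixels, 1L)

  dec <- generate_decay(lifetime_mixture(2), 1000, m, mode = "sampled")
  unif <- tcspc_image(array(rep(dec$counts, each = 4), c(2, 2, 32)), m)
  up <- phasor_image(unif, harmonic = 1)
  ump <- aggregate_measurement(up, 0, "cond")
  expect_equal(unname(ump$phasors[["1"]]["g"]), up$g[1, 1], tolerance = 1e-12)
})

test_that("the universal circle polyline is the upper semicircle", {
  uc <- universal_circle(501L)
  expect_equal((uc$g - 0.5)^2 + uc$s^2, rep(0.25, 501), tolerance = 1e-12)
  expect_true(all(uc$s >= 0))
  expect_equal(unlist(uc[1, ]), c(g = 0, s = 0), tolerance = 1e-12)
  expect_equal(unlist(uc[501, ]), c(g = 1, s = 0), tolerance = 1e-12)
  expect_equal(max(uc$s), 0.5, tolerance = 1e-5)
  expect_error(universal_circle(1), "at least 2")
})
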