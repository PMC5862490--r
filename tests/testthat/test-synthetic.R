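test_that("lifetime mixtures enforce matching lengths and unit fractions", {
  expect_error(lifetime_mixture(c(1, 2), c(0.6, 0.5)), "sum to 1")
  expect_error(lifetime_mixture(c(1, -2), c(0.5, 0.5)), "positive")
  expect_error(lifetime_mixture(c(1, 2), c(1)), "equal length")
  mx <- lifetime_mixture(c(0.3, 2), c(0.7, 0.3))
  expect_equal(free_fraction(mx), 0.7)
})

test_that("expected-mode decay matches the closed-form single-exponential phasor", {
  m <- acq_meta()
  om <- angular_frequency(m, 1)
  for (tau in c(0.5, 1, 2)) {
    d <- generate_decay(lifetime_mixture(tau), 1e6, m, mode = "expected")
    expect_equal(sum(d$counts), 1e6, tolerance = 1e-9)
    p <- pixel_phasor(d, 1)
    cf <- oracle_single_exp(tau, om)
    expect_equal(p$g, unname(cf["g"]), tolerance = 1e-3)
    expect_equal(p$s, unname(cf["s"]), tolerance = 1e-3)
  }
})

test_that("degenerate decay inputs behave: zero photons, duplicated components", {
  m <- acq_meta(n_bins = 64L)
  z <- generate_decay(lifetime_mixture(2), 0, m, mode = "expected")
  expect_true(all(z$counts == 0))
  a <- generate_decay(lifetime_mixture(c(2, 2), c(0.5, 0.5)), 1e5, m,
                      mode = "expected")
  b <- generate_decay(lifetime_mixture(2), 1e5, m, mode = "expected")
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
  expect_error(generate_decay(lifetime_mixture(2), -5, m), "nonnegative")
})

test_that("expected bin masses agree with adaptive numerical integration of the folded model", {
  m <- acq_meta(n_bins = 32L)
  for (irf in list(c(fwhm = 0, offset = 0), c(fwhm = 0.2, offset = 0.5))) {
    for (tau in c(0.4, 3.5)) {
      mine <- flimphasor:::.component_bin_mass(tau, m, irf)
      orc <- oracle_bin_mass(tau, m, irf)
      expect_equal(mine, orc / sum(orc), tolerance = 1e-9)
    }
  }
})

test_that("sampled mode is Poisson: index of dispersion near 1", {
  m <- acq_meta(n_bins = 32L)
  mx <- lifetime_mixture(c(0.5, 3), c(0.4, 0.6))
  set.seed(7)
  reps <- t(replicate(300, generate_decay(mx, 3000, m, mode = "sampled")$counts))
  mu <- colMeans(reps)
  keep <- mu > 5
  iod <- apply(reps[, keep], 2, var) / mu[keep]
  expect_gt(mean(iod), 0.85)
  expect_lt(mean(iod), 1.15)
})

test_that("raising the shortest-lifetime fraction strictly raises g", {
  m <- acq_meta()
  om <- angular_frequency(m, 1)
  taus <- c(0.3, 0.8, 2, 4)
  g_prev <- -Inf
  for (f1 in seq(0.05, 0.85, by = 0.1)) {
    rest <- (1 - f1) * c(0.2, 0.5, 0.3)
    d <- generate_decay(lifetime_mixture(taus, c(f1, rest)), 1e6, m,
                        mode = "expected")
    g <- pixel_phasor(d, 1)$g
    expect_gt(g, g_prev)
    g_prev <- g
  }
})

test_that("TAC truncation zeroes exactly the leading bins", {
  m <- acq_meta(n_bins = 32L)
  d <- generate_decay(lifetime_mixture(1.5), 1e5, m, mode = "expected")
  expect_equal(apply_tac_truncation(d, 0)$counts, d$counts)
  t5 <- apply_tac_truncation(d, 5)
  expect_true(all(t5$counts[1:5] == 0))
  expect_equal(t5$counts[6:32], d$counts[6:32])
  expect_equal(sum(d$counts) - sum(t5$counts), sum(d$counts[1:5]))
  expect_error(apply_tac_truncation(d, 32), "n_bins")
})

test_that("scenes are deterministic given the seed and honor the vessel mask", {
  spec <- default_scene_spec(default_presets()$etc_inhibition,
                             height = 8L, width = 8L, brightness = 200,
                             vessel_frac = 0, seed = 5L)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$baseline$counts, s2$baseline$counts)
  expect_identical(s1$treated$counts, s2$treated$counts)
  expect_false(any(s1$masks$vessel$include))
})

test_that("treated/baseline photon ratio matches the preset intensity ratio", {
  preset <- default_presets()$etc_inhibition
  spec <- default_scene_spec(preset, height = 24L, width = 24L,
                             brightness = 600, vessel_frac = 0, seed = 9L)
  sc <- generate_scene(spec)
  nb <- total_photons(sc$baseline)
  nt <- total_photons(sc$treated)
  r <- preset$intensity_ratio
  # 3-sigma Poisson band on the ratio around the configured budget
  sd_ratio <- r * sqrt(1 / nb + 1 / nt)
  expect_lt(abs(nt / nb - r), 3 * sd_ratio)
})

test_that("scene specs validate the region partition and truncation bound", {
  vm <- pixel_mask(matrix(FALSE, 4, 4), "vessel")
  mx <- lifetime_mixture(2)
  expect_error(
    scene_spec(4, 4, regions = list(a = list(pixels = 1:3, mixture = mx,
                                             brightness = 10)),
               vessel_mask = vm),
    "partition")
  expect_error(
    scene_spec(4, 4, regions = list(a = list(pixels = NULL, mixture = mx,
                                             brightness = 10)),
               tac_truncated_bins = 100L),
    "n_bins/4")
})

test_that("studies have the paper-scale design and dispersion behaves", {
  st <- make_study(c("tca_inhibition"), n_animals = 3, n_locations = 3,
                   height = 4, width = 4, brightness = 50, vessel_frac = 0,
                   seed = 3)
  expect_equal(length(st$measurements), 9L)  # 3 animals x 3 locations
  # zero dispersion: every scene of the condition shares identical truth
  st0 <- make_study(c("etc_inhibition"), 2, 2, height = 4, width = 4,
                    brightness = 50, vessel_frac = 0,
                    dispersion_animal = 0, dispersion_location = 0,
                    intensity_jitter = 0, seed = 4)
  ff <- vapply(st0$measurements,
               function(r) free_fraction(r$truth$treated_mixture), 1)
  expect_equal(max(ff) - min(ff), 0)
  # Monte-Carlo: realized free fractions center on the preset value
  stmc <- make_study(c("etc_inhibition"), 10, 3, height = 4, width = 4,
                     brightness = 50, vessel_frac = 0,
                     dispersion_animal = 0, dispersion_location = 0.05,
                     seed = 6)
  ffs <- vapply(stmc$measurements,
                function(r) free_fraction(r$truth$treated_mixture), 1)
  target <- free_fraction(default_presets()$etc_inhibition$mixture)
  expect_lt(abs(mean(ffs) - target), 2 * sd(ffs) / sqrt(length(ffs)))
  expect_error(make_study(list()), "empty preset")
})
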