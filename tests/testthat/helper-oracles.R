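# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (CDF-difference bin masses, sorting
# networks, matrix phasor sums) so each test is a genuine cross-check.

# closed-form single-exponential phasor (re-derived locally)
oracle_single_exp <- function(tau, omega) {
  wt <- omega * tau
  c(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

# phasor of a histogram by direct elementwise summation
oracle_phasor <- function(counts, meta, harmonic) {
  om <- harmonic * 2 * pi * meta$rep_rate * 1e-9
  tc <- (seq_along(counts) - 0.5) * meta$window / meta$n_bins
  c(g = sum(counts * cos(om * tc)) / sum(counts),
    s = sum(counts * sin(om * tc)) / sum(counts))
}

# exponentially-modified Gaussian pdf, folded over the pulse train
oracle_folded_density <- function(t, tau, mu, sigma, period, n_wrap = 60) {
  val <- 0
  for (m in -1:n_wrap) {
    tt <- t + m * period
    if (sigma <= 0) {
      val <- val + ifelse(tt > mu, exp(-(tt - mu) / tau) / tau, 0)
    } else {
      z <- (tt - mu) / sigma
      k <- sigma^2 / (2 * tau^2) - (tt - mu) / tau
      val <- val + exp(k + pnorm(z - sigma / tau, log.p = TRUE)) / tau
    }
  }
  val
}

# per-bin mass by adaptive numerical integration of the folded density
oracle_bin_mass <- function(tau, meta, irf) {
  period <- 1 / (meta$rep_rate * 1e-9)
  sigma <- irf[["fwhm"]] / (2 * sqrt(2 * log(2)))
  edges <- seq(0, meta$window, length.out = meta$n_bins + 1)
  vapply(seq_len(meta$n_bins), function(i)
    integrate(oracle_folded_density, edges[i], edges[i + 1], tau = tau,
              mu = irf[["offset"]], sigma = sigma, period = period,
              rel.tol = 1e-12, abs.tol = 1e-14)$value,
    numeric(1))
}

# sliding-window median with edge replication, straightforward loops
oracle_median_filter <- function(m, k) {
  r <- (k - 1) %/% 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ri <- pmin(pmax((i - r):(i + r), 1), nrow(m))
    ci <- pmin(pmax((j - r):(j + r), 1), ncol(m))
    out[i, j] <- median(m[ri, ci])
  }
  out
}

# sliding-window neighborhood sum of one pixel's decay, by loops
oracle_binned_decay <- function(arr, i, j, w) {
  r <- (w - 1) %/% 2
  ri <- pmin(pmax((i - r):(i + r), 1), dim(arr)[1])
  ci <- pmin(pmax((j - r):(j + r), 1), dim(arr)[2])
  out <- numeric(dim(arr)[3])
  for (a in ri) for (b in ci) out <- out + arr[a, b, ]
  out
}

# permutation p-value for the two-sample Hotelling statistic
oracle_permutation_p <- function(a, b, n_perm = 10000) {
  obs <- hotelling_t2(a, b)$t2
  pool <- rbind(a, b)
  na <- nrow(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nrow(pool), na)
    t2 <- hotelling_t2(pool[idx, , drop = FALSE],
                       pool[-idx, , drop = FALSE])$t2
    if (t2 >= obs) hits <- hits + 1
  }
  hits / n_perm
}

# a tiny measurement table with the layout of measurement_table()
fake_measurements <- function(n_per = 9, conditions = c("baseline",
                              "tca_inhibition", "etc_inhibition",
                              "oxphos_uncoupling"),
                              centers = NULL, sd = 0.01, seed = 1) {
  set.seed(seed)
  if (is.null(centers)) {
    centers <- list(baseline = c(0.60, 0.41, 0.0),
                    tca_inhibition = c(0.65, 0.40, 0.15),
                    etc_inhibition = c(0.70, 0.36, 0.40),
                    oxphos_uncoupling = c(0.67, 0.38, -0.15),
                    glycolysis_inhibition = c(0.60, 0.41, 0.0),
                    seizure_like = c(0.695, 0.365, 0.38))
  }
  rows <- lapply(conditions, function(cn) {
    ct <- centers[[cn]]
    data.frame(condition = cn,
               animal_id = paste0(cn, "_a", rep(1:3, length.out = n_per)),
               location_id = paste0("loc", seq_len(n_per)),
               g1 = rnorm(n_per, ct[1], sd), s1 = rnorm(n_per, ct[2], sd),
               g2 = rnorm(n_per, ct[1] - 0.2, sd),
               s2 = rnorm(n_per, ct[2] - 0.03, sd),
               delta_intensity = rnorm(n_per, ct[3], sd),
               n_valid_pixels = 256L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
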