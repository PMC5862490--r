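# Phasor coordinates: discrete Fourier sums over TCSPC histograms, the
# closed-form single-exponential and vectorial-sum mixture phasors,
# referencing (calibration) against a standard, and per-measurement
# aggregation.

#' Phasor coordinates of one decay histogram
#'
#' The intensity-normalized cosine and sine Fourier components of the decay
#' at \eqn{\omega = k \cdot 2\pi f}:
#' \deqn{g = \sum_i c_i \cos(\omega t_i) / \sum_i c_i, \quad
#'       s = \sum_i c_i \sin(\omega t_i) / \sum_i c_i}
#' with \eqn{t_i} the bin centers. The sums always run over the entire
#' histogram, including any truncated early region; no background is
#' subtracted. By the triangle inequality \eqn{\sqrt{g^2+s^2} \le 1} for any
#' nonnegative histogram (numerical tolerance 1e-9).
#'
#' @param decay A [decay_histogram()] with at least one positive entry.
#' @param harmonic Integer harmonic index `k >= 1`.
#' @return A [phasor_point()].
#' @examples
#' d <- generate_decay(lifetime_mixture(2.0), 1e5, mode = "expected")
#' pixel_phasor(d, 1)
#' @export
pixel_phasor <- function(decay, harmonic = decay$meta$harmonic_default) {
  stopifnot(inherits(decay, "decay_histogram"))
  total <- sum(decay$counts)
  if (total <= 0) stop("empty histogram: phasor undefined", call. = FALSE)
  omega <- angular_frequency(decay$meta, harmonic)
  tc <- bin_centers(decay$meta)
  phasor_point(g = sum(decay$counts * cos(omega * tc)) / total,
               s = sum(decay$counts * sin(omega * tc)) / total,
               harmonic = harmonic, photons = total)
}

#' Per-pixel phasor image
#'
#' Applies the discrete phasor transform of [pixel_phasor()] at every valid
#' pixel of a (preprocessed) stack. Invalid pixels carry `NA`.
#'
#' @param image A [tcspc_image()].
#' @param valid Optional [pixel_mask()]; defaults to all pixels. Pixels with
#'   zero total counts are additionally dropped.
#' @param harmonic Integer harmonic index.
#' @return An object of class `phasor_image`: matrices `g` and `s`, the
#'   `valid` mask actually used, `harmonic`, `calibrated` flag and `meta`.
#' @export
phasor_image <- function(image, valid = NULL,
                         harmonic = image$meta$harmonic_default) {
  stopifnot(inherits(image, "tcspc_image"))
  d <- dim(image$counts)
  if (is.null(valid)) valid <- pixel_mask(matrix(TRUE, d[1], d[2]))
  stopifnot(inherits(valid, "pixel_mask"))
  .check_mask_shape(valid, image)
  flat <- matrix(image$counts, d[1] * d[2], d[3])
  totals <- rowSums(flat)
  keep <- valid$include & matrix(totals > 0, d[1], d[2])
  if (!any(keep)) stop("no valid pixels with photons", call. = FALSE)
  omega <- angular_frequency(image$meta, harmonic)
  tc <- bin_centers(image$meta)
  g <- matrix((flat %*% cos(omega * tc)) / totals, d[1], d[2])
  s <- matrix((flat %*% sin(omega * tc)) / totals, d[1], d[2])
  g[!keep] <- NA_real_; s[!keep] <- NA_real_
  structure(list(g = g, s = s, valid = pixel_mask(keep, "valid"),
                 harmonic = as.integer(harmonic), calibrated = FALSE,
                 meta = image$meta),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf(
    "phasor image %d x %d, harmonic %d, %d valid pixels%s\n",
    nrow(x$g), ncol(x$g), x$harmonic, sum(x$valid$include),
    if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' Closed-form phasor of a single-exponential decay
#'
#' \deqn{g = 1/(1+(\omega\tau)^2), \quad s = \omega\tau/(1+(\omega\tau)^2)}
#' For every \eqn{\tau \ge 0} the point lies on the universal semicircle
#' \eqn{(g-1/2)^2 + s^2 = 1/4}: \eqn{(1, 0)} in the zero-lifetime limit,
#' apex \eqn{(1/2, 1/2)} at \eqn{\omega\tau = 1}, and \eqn{(0, 0)} as
#' \eqn{\tau \to \infty}.
#'
#' @param tau Lifetime(s) in ns, `>= 0`; vectorized.
#' @param omega Angular frequency in rad/ns, `> 0`.
#' @return List with numeric vectors `g` and `s`.
#' @export
single_exp_phasor <- function(tau, omega) {
  tau <- as.numeric(tau)
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("'tau' must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a single positive frequency", call. = FALSE)
  wt <- omega * tau
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Vectorial-sum phasor of a lifetime mixture
#'
#' The phasor of a multi-exponential decay is the fractionally weighted
#' vectorial sum of its component phasors,
#' \eqn{(g, s) = \sum_i f_i \cdot (g_i, s_i)}, and therefore lies in the
#' convex hull of the component points on the universal circle.
#'
#' @param mixture A [lifetime_mixture()].
#' @param omega Angular frequency in rad/ns.
#' @return List with scalars `g` and `s`.
#' @export
mixture_phasor <- function(mixture, omega) {
  stopifnot(inherits(mixture, "lifetime_mixture"))
  comp <- single_exp_phasor(mixture$lifetimes, omega)
  list(g = sum(mixture$fractions * comp$g),
       s = sum(mixture$fractions * comp$s))
}

#' Calibration transform from a measured reference standard
#'
#' Treating phasors as complex numbers \eqn{z = g + is}, the transform is the
#' single complex correction factor \eqn{z \mapsto z \cdot
#' z_{theory}/z_{measured}} that maps the measured phasor of the reference
#' standard onto the phasor of its known decay model at the same harmonic --
#' the standard phasor-referencing construction. It corrects both the phase
#' shift and the modulation loss introduced by the instrument response and
#' early-bin truncation (exactly for the IRF, whose circular convolution is a
#' pure complex multiplication of the Fourier coefficients; approximately for
#' truncation).
#'
#' @param measured_ref [phasor_point()] of the measured standard (nonzero
#'   modulus).
#' @param reference_model [lifetime_mixture()] describing the standard's true
#'   decay; defaults to [nadh_reference_model()].
#' @param meta An [acq_meta()] used to derive \eqn{\omega}.
#' @param harmonic Harmonic index; defaults to the measured point's.
#' @return An object of class `calibration_transform` with `phase_shift`
#'   (radians), `modulation_scale` (> 0) and `harmonic`.
#' @export
calibrate <- function(measured_ref, reference_model = nadh_reference_model(),
                      meta = acq_meta(), harmonic = measured_ref$harmonic) {
  stopifnot(inherits(measured_ref, "phasor_point"))
  z_meas <- complex(real = measured_ref$g, imaginary = measured_ref$s)
  if (Mod(z_meas) == 0)
    stop("measured reference has zero modulus", call. = FALSE)
  th <- mixture_phasor(reference_model, angular_frequency(meta, harmonic))
  corr <- complex(real = th$g, imaginary = th$s) / z_meas
  structure(list(phase_shift = Arg(corr), modulation_scale = Mod(corr),
                 harmonic = as.integer(harmonic)),
            class = "calibration_transform")
}

#' @export
print.calibration_transform <- function(x, ...) {
  cat(sprintf(
    "calibration (harmonic %d): phase %+.5f rad, modulation scale %.5f\n",
    x$harmonic, x$phase_shift, x$modulation_scale))
  invisible(x)
}

#' Apply a calibration transform
#'
#' Complex multiplication by the correction factor, per point or per valid
#' pixel. Harmonics must match.
#'
#' @param x A [phasor_point()] or `phasor_image`.
#' @param transform A [calibrate()] result.
#' @return Object of the same class, calibrated.
#' @export
apply_calibration <- function(x, transform) UseMethod("apply_calibration")

.cal_factor <- function(transform)
  complex(modulus = transform$modulation_scale, argument = transform$phase_shift)

#' @export
apply_calibration.phasor_point <- function(x, transform) {
  stopifnot(inherits(transform, "calibration_transform"))
  if (x$harmonic != transform$harmonic)
    stop("harmonic mismatch between phasor and calibration", call. = FALSE)
  z <- complex(real = x$g, imaginary = x$s) * .cal_factor(transform)
  phasor_point(Re(z), Im(z), x$harmonic, x$photons)
}

#' @export
apply_calibration.phasor_image <- function(x, transform) {
  stopifnot(inherits(transform, "calibration_transform"))
  if (x$harmonic != transform$harmonic)
    stop("harmonic mismatch between phasor image and calibration", call. = FALSE)
  z <- complex(real = x$g, imaginary = x$s) * .cal_factor(transform)
  x$g[] <- Re(z); x$s[] <- Im(z)
  x$calibrated <- TRUE
  x
}

#' Aggregate a phasor image into one measurement
#'
#' The unweighted arithmetic mean of `g` and `s` over valid pixels, per
#' harmonic, yielding a single phasor coordinate pair per imaging session
#' (photon-weighted averaging is available via `weighted = TRUE`, using the
#' stacks' per-pixel totals stored in the images if present).
#'
#' @param phasors A `phasor_image` or a named list of them (one per harmonic,
#'   e.g. `list("1" = ..., "2" = ...)`).
#' @param delta_I Relative intensity change from [delta_intensity()].
#' @param condition,animal_id,location_id Labels for the measurement.
#' @param valid Optional [pixel_mask()] restricting the average further.
#' @return A [measurement_point()].
#' @export
aggregate_measurement <- function(phasors, delta_I, condition,
                                  animal_id = "a1", location_id = "loc1",
                                  valid = NULL) {
  if (inherits(phasors, "phasor_image"))
    phasors <- stats::setNames(list(phasors), as.character(phasors$harmonic))
  stopifnot(is.list(phasors), length(phasors) >= 1L)
  names(phasors) <- vapply(phasors, function(p) as.character(p$harmonic), "")
  out <- list()
  n_valid <- NA_integer_
  for (h in names(phasors)) {
    pim <- phasors[[h]]
    keep <- pim$valid$include
    if (!is.null(valid)) keep <- keep & valid$include
    idx <- which(keep)
    if (length(idx) == 0L) stop("no valid pixels to aggregate", call. = FALSE)
    out[[h]] <- c(g = mean(pim$g[idx]), s = mean(pim$s[idx]))
    n_valid <- length(idx)
  }
  measurement_point(condition, animal_id, location_id, out, delta_I, n_valid)
}

#' Polyline along the universal semicircle
#'
#' Points satisfying \eqn{(g - 1/2)^2 + s^2 = 1/4}, \eqn{s \ge 0}, running
#' from \eqn{(0, 0)} to \eqn{(1, 0)}; used for plot overlays and
#' distance-to-circle diagnostics.
#'
#' @param n_points Number of points, `>= 2`.
#' @return data.frame with columns `g` and `s`.
#' @export
universal_circle <- function(n_points = 181L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("'n_points' must be at least 2", call. = FALSE)
  theta <- seq(pi, 0, length.out = n_points)
  data.frame(g = 0.5 + 0.5 * cos(theta), s = 0.5 * sin(theta))
}

#' Phasor scatter plot with universal-circle overlay
#'
#' Best-effort graphics: one point per measurement, colored by condition,
#' with optional standard deviational ellipses. All plotted coordinates are
#' also written as CSV when `csv` is given, so the rendering is never
#' load-bearing.
#'
#' @param measurements Measurement data.frame (see [measurement_table()]).
#' @param harmonic Harmonic to plot.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @param ellipses Draw per-condition standard deviational ellipses.
#' @param csv Optional CSV path for the plotted coordinates.
#' @return Invisibly, the plotted data.frame.
#' @export
plot_phasor <- function(measurements, harmonic = 1L, file = NULL,
                        ellipses = TRUE, csv = NULL) {
  gcol <- paste0("g", harmonic); scol <- paste0("s", harmonic)
  if (!all(c(gcol, scol) %in% names(measurements)))
    stop(sprintf("measurement table lacks harmonic %d columns", harmonic),
         call. = FALSE)
  df <- data.frame(condition = measurements$condition,
                   g = measurements[[gcol]], s = measurements[[scol]])
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  conds <- sort(unique(df$condition))
  cols <- grDevices::hcl.colors(max(3L, length(conds)), "Dark 3")[seq_along(conds)]
  uc <- universal_circle(361L)
  graphics::plot(uc$g, uc$s, type = "l", col = "grey40", lty = 2,
                 xlim = c(0, 1), ylim = c(0, 0.6), xlab = "g", ylab = "s",
                 main = sprintf("NADH phasor, harmonic %d", harmonic))
  for (i in seq_along(conds)) {
    sel <- df$condition == conds[i]
    graphics::points(df$g[sel], df$s[sel], col = cols[i], pch = 19)
    if (ellipses && sum(sel) >= 3) {
      e <- try(std_dev_ellipse(cbind(df$g[sel], df$s[sel])), silent = TRUE)
      if (!inherits(e, "try-error")) {
        ep <- ellipse_points(e)
        graphics::lines(ep$g, ep$s, col = cols[i])
      }
    }
  }
  graphics::legend("topright", legend = conds, col = cols, pch = 19, cex = 0.7)
  invisible(df)
}
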