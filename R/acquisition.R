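#' TCSPC acquisition metadata
#'
#' Describes the timing geometry of a time-correlated single photon counting
#' (TCSPC) acquisition: the pulsed-laser repetition rate, the number of
#' histogram time bins, and the length of the measurement window. Every
#' phasor frequency used by the package is derived from these values as
#' \eqn{\omega = k \cdot 2\pi f} with \eqn{k} the harmonic index; the angular
#' frequency is never stored.
#'
#' The default geometry -- 80 MHz repetition rate and 256 bins spanning a
#' 12.5 ns window -- matches a standard Ti:Sapphire two-photon excitation
#' source, whose pulse period \eqn{1/f} equals the measurement window.
#'
#' @param rep_rate Laser repetition rate in Hz; must be positive.
#' @param n_bins Number of TCSPC histogram bins; at least 2.
#' @param window Measurement window length in ns; must be positive.
#' @param harmonic_default Harmonic index used when none is given explicitly.
#'
#' @return An object of class `acq_meta`.
#' @examples
#' m <- acq_meta()
#' bin_width(m)             # 12.5/256 ns
#' angular_frequency(m, 2)  # 4 * pi * 0.08 rad/ns
#' @export
acq_meta <- function(rep_rate = 80e6, n_bins = 256L, window = 12.5,
                     harmonic_default = 1L) {
  if (!is.numeric(rep_rate) || length(rep_rate) != 1L || rep_rate <= 0)
    stop("'rep_rate' must be a single positive frequency in Hz", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("'window' must be a single positive time in ns", call. = FALSE)
  harmonic_default <- as.integer(harmonic_default)
  if (is.na(harmonic_default) || harmonic_default < 1L)
    stop("'harmonic_default' must be an integer >= 1", call. = FALSE)
  structure(
    list(rep_rate = rep_rate, n_bins = n_bins, window = window,
         harmonic_default = harmonic_default),
    class = "acq_meta"
  )
}

#' @export
print.acq_meta <- function(x, ...) {
  cat(sprintf(
    "TCSPC acquisition: %.4g MHz repetition, %d bins over %.4g ns (dt = %.4g ps)\n",
    x$rep_rate / 1e6, x$n_bins, x$window, 1e3 * bin_width(x)))
  invisible(x)
}

#' Histogram bin width
#'
#' @param meta An [acq_meta()] object.
#' @return Bin width `window / n_bins` in ns.
#' @export
bin_width <- function(meta) {
  stopifnot(inherits(meta, "acq_meta"))
  meta$window / meta$n_bins
}

#' Representative bin times
#'
#' Bin `i` (0-based) spans `[i * dt, (i + 1) * dt)`; its representative time is
#' the bin center `(i + 0.5) * dt`, which keeps the discretization error of
#' the phasor Fourier sums symmetric.
#'
#' @param meta An [acq_meta()] object.
#' @return Numeric vector of `n_bins` bin-center times in ns.
#' @export
bin_centers <- function(meta) {
  stopifnot(inherits(meta, "acq_meta"))
  (seq_len(meta$n_bins) - 0.5) * bin_width(meta)
}

#' Angular frequency of a harmonic
#'
#' @param meta An [acq_meta()] object.
#' @param harmonic Integer harmonic index `k >= 1`.
#' @return \eqn{\omega = k \cdot 2\pi f} in rad/ns.
#' @export
angular_frequency <- function(meta, harmonic = meta$harmonic_default) {
  stopifnot(inherits(meta, "acq_meta"))
  harmonic <- as.integer(harmonic)
  if (any(is.na(harmonic)) || any(harmonic < 1L))
    stop("'harmonic' must be an integer >= 1", call. = FALSE)
  harmonic * 2 * pi * meta$rep_rate * 1e-9
}
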