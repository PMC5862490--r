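# Core data model and file I/O: TCSPC stacks, masks, decay histograms,
# phasor points, measurement tables.

.check_counts <- function(counts, what) {
  if (!is.numeric(counts))
    stop(sprintf("%s must be numeric", what), call. = FALSE)
  if (anyNA(counts))
    stop(sprintf("%s contains NA values", what), call. = FALSE)
  if (any(counts < 0))
    stop(sprintf("%s contains negative values", what), call. = FALSE)
  invisible(TRUE)
}

#' TCSPC photon-count image stack
#'
#' A height x width x time array of nonnegative integer photon counts with
#' its acquisition metadata. The third dimension must equal `meta$n_bins`.
#'
#' @param counts 3-D numeric array `H x W x T` of nonnegative integers.
#' @param meta An [acq_meta()] object; `meta$n_bins` must equal `dim(counts)[3]`.
#' @return An object of class `tcspc_image` with elements `counts` and `meta`.
#' @export
tcspc_image <- function(counts, meta = acq_meta()) {
  stopifnot(inherits(meta, "acq_meta"))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("'counts' must be a 3-D array (height x width x time)", call. = FALSE)
  .check_counts(counts, "'counts'")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("'counts' must be integer photon counts", call. = FALSE)
  if (dim(counts)[3] != meta$n_bins)
    stop(sprintf("stack has %d time bins but meta declares %d",
                 dim(counts)[3], meta$n_bins), call. = FALSE)
  structure(list(counts = counts, meta = meta), class = "tcspc_image")
}

#' @export
print.tcspc_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("TCSPC stack %d x %d pixels, %d time bins, %.4g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Total photon count of a stack
#' @param image A [tcspc_image()].
#' @return Scalar sum of all counts over pixels and bins.
#' @export
total_photons <- function(image) {
  stopifnot(inherits(image, "tcspc_image"))
  sum(image$counts)
}

#' Pixel inclusion mask
#'
#' @param include Logical matrix, `TRUE` for pixels carrying the label.
#' @param label Short description, e.g. `"vessel"`, `"valid"`, `"astrocyte"`.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(include, label = "valid") {
  if (!is.matrix(include) || !is.logical(include))
    stop("'include' must be a logical matrix", call. = FALSE)
  if (anyNA(include)) stop("'include' contains NA", call. = FALSE)
  structure(list(include = include, label = as.character(label)[1]),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("pixel mask '%s': %d / %d pixels\n", x$label,
              sum(x$include), length(x$include)))
  invisible(x)
}

.check_mask_shape <- function(mask, image) {
  if (!identical(dim(mask$include), dim(image$counts)[1:2]))
    stop("mask shape does not match image", call. = FALSE)
  invisible(TRUE)
}

#' Single-pixel (or aggregate) decay histogram
#'
#' Counts need not be integers: expected-mode simulated decays are real
#' valued. All entries must be nonnegative.
#'
#' @param counts Numeric vector of length `meta$n_bins`.
#' @param meta An [acq_meta()] object.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, meta = acq_meta()) {
  stopifnot(inherits(meta, "acq_meta"))
  counts <- as.numeric(counts)
  .check_counts(counts, "'counts'")
  if (length(counts) != meta$n_bins)
    stop(sprintf("histogram has %d bins but meta declares %d",
                 length(counts), meta$n_bins), call. = FALSE)
  structure(list(counts = counts, meta = meta), class = "decay_histogram")
}

#' Phasor coordinates of one decay
#'
#' For any nonnegative histogram the modulus `sqrt(g^2 + s^2)` is bounded by
#' 1 (triangle inequality); a numerical tolerance of 1e-9 is allowed.
#' Calibrated phasors may exceed the bound slightly when the modulation scale
#' is greater than one, so the constructor does not enforce it.
#'
#' @param g,s Dimensionless phasor coordinates.
#' @param harmonic Integer harmonic index the coordinates were computed at.
#' @param photons Total photon count behind the coordinates.
#' @return An object of class `phasor_point`.
#' @export
phasor_point <- function(g, s, harmonic = 1L, photons = NA_real_) {
  if (!is.finite(g) || !is.finite(s))
    stop("phasor coordinates must be finite", call. = FALSE)
  structure(list(g = as.numeric(g), s = as.numeric(s),
                 harmonic = as.integer(harmonic),
                 photons = as.numeric(photons)),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("phasor (g = %.5f, s = %.5f) at harmonic %d [%s photons]\n",
              x$g, x$s, x$harmonic, format(x$photons)))
  invisible(x)
}

#' One imaging session's summary features
#'
#' The row type for the statistics and classification stages: per-harmonic
#' pixel-averaged phasor coordinates, the relative intensity change from the
#' paired baseline acquisition, and condition/animal/location labels.
#'
#' @param condition Condition label (e.g. `"baseline"`, `"etc_inhibition"`).
#' @param animal_id,location_id Replicate labels.
#' @param phasors Named list mapping harmonic (as character) to `c(g =, s =)`;
#'   must contain harmonic `"1"`.
#' @param delta_intensity Relative intensity change, `>= -1`.
#' @param n_valid_pixels Number of pixels averaged.
#' @return An object of class `measurement_point`.
#' @export
measurement_point <- function(condition, animal_id, location_id, phasors,
                              delta_intensity, n_valid_pixels = NA_integer_) {
  if (!is.list(phasors) || is.null(names(phasors)) || !("1" %in% names(phasors)))
    stop("'phasors' must be a named list containing harmonic \"1\"", call. = FALSE)
  for (h in names(phasors)) {
    p <- phasors[[h]]
    if (length(p) != 2L || anyNA(p))
      stop(sprintf("phasor entry for harmonic %s must be c(g, s)", h),
           call. = FALSE)
  }
  if (!is.finite(delta_intensity) || delta_intensity < -1)
    stop("'delta_intensity' must be finite and >= -1", call. = FALSE)
  structure(
    list(condition = as.character(condition),
         animal_id = as.character(animal_id),
         location_id = as.character(location_id),
         phasors = phasors,
         delta_intensity = as.numeric(delta_intensity),
         n_valid_pixels = as.integer(n_valid_pixels)),
    class = "measurement_point"
  )
}

#' Assemble measurement points into a table
#'
#' @param points List of [measurement_point()] objects sharing one harmonic set.
#' @return A data.frame with columns `condition`, `animal_id`, `location_id`,
#'   `g<k>`/`s<k>` per harmonic, `delta_intensity`, `n_valid_pixels`.
#' @export
measurement_table <- function(points) {
  if (length(points) == 0L) stop("no measurement points", call. = FALSE)
  if (inherits(points, "measurement_point")) points <- list(points)
  harms <- lapply(points, function(p) sort(as.integer(names(p$phasors))))
  if (!all(vapply(harms, identical, logical(1), harms[[1]])))
    stop("measurement points carry inconsistent harmonic sets", call. = FALSE)
  hs <- harms[[1]]
  rows <- lapply(points, function(p) {
    vals <- unlist(lapply(as.character(hs), function(h) {
      v <- p$phasors[[h]]
      stats::setNames(as.numeric(v), paste0(c("g", "s"), h))
    }))
    data.frame(condition = p$condition, animal_id = p$animal_id,
               location_id = p$location_id, t(vals),
               delta_intensity = p$delta_intensity,
               n_valid_pixels = p$n_valid_pixels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a measurement table as CSV
#'
#' Fixed header: `condition, animal_id, location_id, g<k>, s<k> ..., `
#' `delta_intensity, n_valid_pixels`. Values are written with full double
#' precision (15 significant digits).
#'
#' @param rows List of [measurement_point()]s or a data.frame from
#'   [measurement_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(rows, path) {
  if (is.data.frame(rows)) tab <- rows
  else tab <- measurement_table(rows)
  if (nrow(tab) == 0L) stop("empty measurement table", call. = FALSE)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, 15))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_measurement_table()]
#' @param path CSV path.
#' @return data.frame in the same layout.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Harmonics present in a measurement table
#' @param table Measurement data.frame.
#' @return Sorted integer vector of harmonics `k` with `g<k>`/`s<k>` columns.
#' @export
table_harmonics <- function(table) {
  g <- grep("^g[0-9]+$", names(table), value = TRUE)
  sort(as.integer(sub("^g", "", g)))
}

# ---- stack file I/O: multi-page TIFF + JSON sidecar --------------------------

.sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a TCSPC stack as multi-page TIFF with a JSON metadata sidecar
#'
#' One 16-bit grayscale page per time bin (counts up to 65535 per bin), plus
#' `<path>.json` carrying the acquisition metadata. The container is
#' inspectable by any TIFF reader; vendor TCSPC formats are out of scope.
#'
#' @param image A [tcspc_image()].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_tcspc_stack <- function(image, path) {
  stopifnot(inherits(image, "tcspc_image"))
  if (max(image$counts) > 65535)
    stop("counts exceed the 16-bit TIFF range", call. = FALSE)
  pages <- lapply(seq_len(image$meta$n_bins),
                  function(t) image$counts[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  jsonlite::write_json(
    list(rep_rate = image$meta$rep_rate, n_bins = image$meta$n_bins,
         window = image$meta$window,
         harmonic_default = image$meta$harmonic_default),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TCSPC stack written by [write_tcspc_stack()]
#'
#' Counts are validated on read: the number of pages must match the declared
#' bin count, and negative or non-integer values are rejected.
#'
#' @param path TIFF path.
#' @param meta Optional [acq_meta()]; if `NULL` the JSON sidecar is read.
#' @return A [tcspc_image()].
#' @export
read_tcspc_stack <- function(path, meta = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(meta)) {
    sp <- .sidecar_path(path)
    if (!file.exists(sp))
      stop("no metadata: supply 'meta' or provide the JSON sidecar", call. = FALSE)
    j <- jsonlite::read_json(sp, simplifyVector = TRUE)
    meta <- acq_meta(j$rep_rate, j$n_bins, j$window, j$harmonic_default)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins)
    stop(sprintf("stack file has %d pages but meta declares %d bins",
                 length(pages), meta$n_bins), call. = FALSE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  .check_counts(arr, "stack file")
  if (any(abs(arr - round(arr)) > 1e-9))
    stop("stack file contains non-integer counts", call. = FALSE)
  tcspc_image(round(arr), meta)
}
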