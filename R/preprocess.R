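# Preprocessing chain: 3x3 median filter -> vessel masking -> 3x3 sliding
# decay binning -> photon-count validity floor. Order is fixed; every step
# uses edge replication so border pixels are not photon-deflated.

# Spatially shifted copy of a 3-D stack (or 2-D plane) with edge replication.
.shift_replicate <- function(x, di, dj) {
  d <- dim(x)
  ri <- pmin(pmax(seq_len(d[1]) + di, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) + dj, 1L), d[2])
  if (length(d) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
}

# Median of 9 same-shaped arrays via a 19-exchange min/max sorting network
# (Paeth), vectorized over all elements at once.
.median9 <- function(p) {
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

.median_filter_plane <- function(m, kernel) {
  if (kernel == 1L) return(m)
  if (kernel == 3L) {
    shifts <- expand.grid(di = -1:1, dj = -1:1)
    p <- lapply(seq_len(9), function(i)
      .shift_replicate(m, shifts$di[i], shifts$dj[i]))
    return(.median9(p))
  }
  r <- (kernel - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ri <- pmin(pmax((i - r):(i + r), 1L), H)
    ci <- pmin(pmax((j - r):(j + r), 1L), W)
    out[i, j] <- stats::median(m[ri, ci])
  }
  out
}

#' Median-filter every time-bin plane of a stack
#'
#' Each of the `n_bins` count planes is filtered independently with a
#' `kernel x kernel` spatial median (edge replication), leaving the time axis
#' untouched. Since the median of a neighborhood is always one of its values,
#' the value set of each plane is conserved.
#'
#' @param image A [tcspc_image()].
#' @param kernel Odd window size, default 3.
#' @return A [tcspc_image()] of the same shape.
#' @export
median_filter_stack <- function(image, kernel = 3L) {
  stopifnot(inherits(image, "tcspc_image"))
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stop("'kernel' must be an odd positive integer", call. = FALSE)
  if (kernel == 1L) return(image)
  arr <- image$counts
  if (kernel == 3L) {
    shifts <- expand.grid(di = -1:1, dj = -1:1)
    p <- lapply(seq_len(9), function(i)
      .shift_replicate(arr, shifts$di[i], shifts$dj[i]))
    out <- .median9(p)
  } else {
    out <- arr
    for (t in seq_len(dim(arr)[3]))
      out[, , t] <- .median_filter_plane(arr[, , t], kernel)
  }
  tcspc_image(out, image$meta)
}

#' Exclude vessel pixels from downstream analysis
#'
#' Vessel pixels are zeroed in the returned stack and excluded from the valid
#' mask; counts of included pixels are untouched.
#'
#' @param image A [tcspc_image()].
#' @param vessel_mask A [pixel_mask()] with `TRUE` marking vessel pixels.
#' @return List with `image` (vessels zeroed) and `valid` (a [pixel_mask()],
#'   `TRUE` for non-vessel pixels). Errors if no pixel remains.
#' @export
apply_mask <- function(image, vessel_mask) {
  stopifnot(inherits(image, "tcspc_image"), inherits(vessel_mask, "pixel_mask"))
  .check_mask_shape(vessel_mask, image)
  keep <- !vessel_mask$include
  if (!any(keep)) stop("mask excludes every pixel", call. = FALSE)
  arr <- image$counts
  if (any(vessel_mask$include)) {
    flat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3])
    flat[which(vessel_mask$include), ] <- 0
    arr[] <- flat
  }
  list(image = tcspc_image(arr, image$meta), valid = pixel_mask(keep, "valid"))
}

#' Sliding-window decay binning with a photon-count floor
#'
#' Each pixel's decay is replaced by the per-bin sum over its
#' `window x window` spatial neighborhood (sliding window with edge
#' replication, image dimensions preserved -- the convention of common TCSPC
#' software, not block downsampling). Pixels whose binned photon total falls
#' below `min_photons` are flagged invalid rather than raising an error: the
#' floor is a quality filter.
#'
#' @param image A [tcspc_image()].
#' @param window Odd neighborhood size, default 3.
#' @param min_photons Validity floor on the binned per-pixel total
#'   (default 5000).
#' @param valid Optional [pixel_mask()] of already-valid pixels to intersect
#'   with the floor.
#' @return List with `image` (binned stack) and `valid` (a [pixel_mask()]).
#' @export
bin_decays <- function(image, window = 3L, min_photons = 5000, valid = NULL) {
  stopifnot(inherits(image, "tcspc_image"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  r <- (window - 1L) %/% 2L
  arr <- image$counts
  out <- array(0, dim(arr))
  for (di in -r:r) for (dj in -r:r)
    out <- out + .shift_replicate(arr, di, dj)
  totals <- apply(out, c(1, 2), sum)
  keep <- totals >= min_photons
  if (!is.null(valid)) {
    stopifnot(inherits(valid, "pixel_mask"))
    .check_mask_shape(valid, image)
    keep <- keep & valid$include
  }
  list(image = tcspc_image(out, image$meta),
       valid = pixel_mask(keep, "valid"))
}

#' Relative intensity change between paired acquisitions
#'
#' \eqn{\Delta I = (\sum treated - \sum baseline) / \sum baseline} over the
#' valid pixels (all bins summed). Dimensionless, bounded below by -1.
#'
#' @param baseline,treated Co-registered [tcspc_image()]s of equal shape.
#' @param valid A [pixel_mask()] shared by both stacks.
#' @return Scalar \eqn{\Delta I}.
#' @export
delta_intensity <- function(baseline, treated, valid) {
  stopifnot(inherits(baseline, "tcspc_image"), inherits(treated, "tcspc_image"),
            inherits(valid, "pixel_mask"))
  if (!identical(dim(baseline$counts), dim(treated$counts)))
    stop("paired stacks must share dimensions", call. = FALSE)
  .check_mask_shape(valid, baseline)
  idx <- which(valid$include)
  if (length(idx) == 0L) stop("no valid pixels", call. = FALSE)
  npix <- prod(dim(baseline$counts)[1:2])
  fb <- matrix(baseline$counts, npix, dim(baseline$counts)[3])
  ft <- matrix(treated$counts, npix, dim(treated$counts)[3])
  sb <- sum(fb[idx, ]); st <- sum(ft[idx, ])
  if (sb <= 0) stop("baseline total over valid pixels is zero", call. = FALSE)
  st / sb - 1
}

#' Run the full preprocessing chain on one paired acquisition
#'
#' Fixed order: median filter, vessel masking, sliding-window binning,
#' photon-count floor. The final valid mask is the intersection of the
#' non-vessel mask with the floor masks of both acquisitions, so that the
#' same pixels enter the baseline and treated statistics. \eqn{\Delta I} is
#' computed from the masked, median-filtered (un-binned) stacks over the
#' final valid mask; sliding-window binning would re-weight pixels without
#' changing the ratio appreciably.
#'
#' @param baseline,treated Paired [tcspc_image()]s.
#' @param vessel_mask Optional [pixel_mask()] of vessel pixels.
#' @param kernel Median filter size (odd, default 3).
#' @param bin_window Binning neighborhood size (odd, default 3).
#' @param min_photons Binned-total validity floor (default 5000).
#' @param median_target `"counts"` (filter the count planes; default) or
#'   `"none"` (skip; phasor-plane filtering is applied downstream by
#'   [analyze_study()] when requested).
#' @return List with binned `baseline` and `treated` stacks, the shared
#'   `valid` [pixel_mask()], `delta_I`, and the masked filtered stacks
#'   (`baseline_filtered`, `treated_filtered`).
#' @export
preprocess_pair <- function(baseline, treated, vessel_mask = NULL,
                            kernel = 3L, bin_window = 3L, min_photons = 5000,
                            median_target = c("counts", "none")) {
  median_target <- match.arg(median_target)
  if (is.null(vessel_mask))
    vessel_mask <- pixel_mask(matrix(FALSE, dim(baseline$counts)[1],
                                     dim(baseline$counts)[2]), "vessel")
  if (median_target == "counts") {
    baseline <- median_filter_stack(baseline, kernel)
    treated <- median_filter_stack(treated, kernel)
  }
  mb <- apply_mask(baseline, vessel_mask)
  mt <- apply_mask(treated, vessel_mask)
  bb <- bin_decays(mb$image, bin_window, min_photons, mb$valid)
  bt <- bin_decays(mt$image, bin_window, min_photons, mt$valid)
  valid <- pixel_mask(bb$valid$include & bt$valid$include, "valid")
  if (!any(valid$include))
    stop("no pixel passes the photon-count floor in both acquisitions",
         call. = FALSE)
  dI <- delta_intensity(mb$image, mt$image, valid)
  list(baseline = bb$image, treated = bt$image, valid = valid, delta_I = dI,
       baseline_filtered = mb$image, treated_filtered = mt$image)
}
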