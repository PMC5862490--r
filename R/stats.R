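# Bivariate dispersion (standard deviational ellipses) and separability
# (two-sample Hotelling T-squared) of condition phasor clusters.

.as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points))
    stop("'points' must be an n x 2 numeric matrix of (g, s)", call. = FALSE)
  if (anyNA(points)) stop("'points' contains NA", call. = FALSE)
  points
}

#' Standard deviational ellipse of a bivariate point set
#'
#' Summarizes 2-D dispersion around the mean center: the major axis is the
#' rotation of the coordinate frame that maximizes the standard deviation of
#' the projected deviations (closed form
#' \eqn{\theta = \frac{1}{2}\,\mathrm{atan2}(2 C_{xy},\, C_{xx} - C_{yy})}
#' from the deviations' sums of squares and cross-products), and the
#' semi-axes are the standard deviations of the deviations projected onto
#' the rotated axes, normalized by \eqn{1/(n-1)}. This is the
#' eigen-equivalent form of the classical geographic standard deviational
#' ellipse: the axes equal the square roots of the eigenvalues of the sample
#' covariance of the deviations, and the angle is that of the principal
#' eigenvector.
#'
#' @param points `n x 2` matrix or data.frame of `(g, s)` with `n >= 3`.
#' @return An object of class `sd_ellipse`: `center` (`c(g, s)`),
#'   `semi_major >= semi_minor >= 0`, `angle` of the major axis versus the
#'   g-axis in `(-pi/2, pi/2]`, and a `degenerate` flag. All points
#'   coincident yields a zero-axes ellipse with a warning.
#' @export
std_dev_ellipse <- function(points) {
  points <- .as_points(points)
  n <- nrow(points)
  if (n < 3L) stop("at least 3 points are required", call. = FALSE)
  center <- colMeans(points)
  dx <- points[, 1] - center[1]
  dy <- points[, 2] - center[2]
  A <- sum(dx^2); B <- sum(dy^2); C <- sum(dx * dy)
  degenerate <- (A + B) < .Machine$double.eps * n
  if (degenerate) {
    warning("all points coincide: zero-axes ellipse", call. = FALSE)
    theta <- 0
    smaj <- smin <- 0
  } else {
    theta <- 0.5 * atan2(2 * C, A - B)
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    smaj <- sqrt(sum(u^2) / (n - 1))
    smin <- sqrt(sum(v^2) / (n - 1))
    if (smin > smaj) {  # guard: rotate by pi/2 so the major axis leads
      tmp <- smaj; smaj <- smin; smin <- tmp
      theta <- theta + pi / 2
    }
  }
  # normalize angle into (-pi/2, pi/2]
  theta <- theta - pi * floor(theta / pi)
  if (theta > pi / 2) theta <- theta - pi
  structure(list(center = stats::setNames(center, c("g", "s")),
                 semi_major = smaj, semi_minor = smin, angle = theta,
                 n = n, degenerate = degenerate),
            class = "sd_ellipse")
}

#' @export
print.sd_ellipse <- function(x, ...) {
  cat(sprintf(
    "SD ellipse: center (%.5f, %.5f), axes %.5f / %.5f, angle %.4f rad (n = %d)%s\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$angle, x$n,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Boundary polyline of a standard deviational ellipse
#' @param ellipse An [std_dev_ellipse()] result.
#' @param n_points Number of boundary points.
#' @return data.frame with columns `g` and `s`.
#' @export
ellipse_points <- function(ellipse, n_points = 120L) {
  stopifnot(inherits(ellipse, "sd_ellipse"))
  t <- seq(0, 2 * pi, length.out = n_points)
  x <- ellipse$semi_major * cos(t)
  y <- ellipse$semi_minor * sin(t)
  data.frame(
    g = ellipse$center[1] + x * cos(ellipse$angle) - y * sin(ellipse$angle),
    s = ellipse$center[2] + x * sin(ellipse$angle) + y * cos(ellipse$angle))
}

#' Two-sample Hotelling T-squared test
#'
#' Tests whether two multivariate samples share a mean, using the pooled
#' sample covariance:
#' \deqn{T^2 = \frac{n_a n_b}{n_a + n_b}\, (\bar{x}_a - \bar{x}_b)' S^{-1}
#'       (\bar{x}_a - \bar{x}_b)}
#' with the F transformation
#' \eqn{F = T^2 (n_a + n_b - p - 1) / ((n_a + n_b - 2) p)} on
#' \eqn{(p,\; n_a + n_b - p - 1)} degrees of freedom.
#'
#' @param group_a,group_b `n x p` matrices or data.frames (rows are
#'   observations), `n_a, n_b >= 3`.
#' @param pseudo_inverse If `TRUE`, a Moore-Penrose pseudo-inverse of the
#'   pooled covariance is used when it is singular (e.g. a degenerate 1-D
#'   embedding); otherwise singularity is an error.
#' @return An object of class `hotelling_test`: `t2`, `f_stat`,
#'   `df = c(numerator, denominator)`, `p_value`, group sizes.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(18), 9, 2)
#' hotelling_t2(a, a)$t2  # identical groups: 0
#' @export
hotelling_t2 <- function(group_a, group_b, pseudo_inverse = FALSE) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != ncol(b))
    stop("groups must be numeric matrices with equal column count", call. = FALSE)
  na <- nrow(a); nb <- nrow(b); p <- ncol(a)
  if (na < 3L || nb < 3L)
    stop("each group needs at least 3 observations", call. = FALSE)
  d <- colMeans(a) - colMeans(b)
  S <- ((na - 1) * stats::cov(a) + (nb - 1) * stats::cov(b)) / (na + nb - 2)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond(S) < 1e-12) {
    if (!pseudo_inverse)
      stop("pooled covariance is singular; set pseudo_inverse = TRUE to use ",
           "a Moore-Penrose fallback", call. = FALSE)
    Sinv <- MASS::ginv(S)
  }
  t2 <- as.numeric((na * nb / (na + nb)) * t(d) %*% Sinv %*% d)
  df1 <- p
  df2 <- na + nb - p - 1
  if (df2 <= 0) stop("too few observations for the F transformation", call. = FALSE)
  f_stat <- t2 * df2 / ((na + nb - 2) * p)
  structure(list(t2 = t2, f_stat = f_stat, df = c(df1, df2),
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 n = c(a = na, b = nb), p = p),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf(
    "Hotelling T2 = %.4f, F(%d, %d) = %.4f, p = %.4g (n = %d vs %d)\n",
    x$t2, x$df[1], x$df[2], x$f_stat, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' Per-condition separability report against baseline
#'
#' For each non-baseline condition and each requested harmonic, the
#' two-sample Hotelling test of the condition's `(g, s)` cluster against the
#' baseline cluster, plus the condition cluster's standard deviational
#' ellipse. Conditions with `p >= alpha` are flagged non-separable. No
#' multiple-testing correction is applied across conditions; `alpha` is 0.05
#' by default.
#'
#' @param measurements Measurement data.frame (see [measurement_table()]).
#' @param baseline_label Condition label of the baseline group (must be
#'   present).
#' @param harmonics Integer vector of harmonics to report.
#' @param alpha Significance level.
#' @return data.frame with one row per condition x harmonic: sizes, `t2`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `significant`, and the ellipse
#'   parameters `center_g`, `center_s`, `semi_major`, `semi_minor`, `angle`.
#' @export
separability_report <- function(measurements, baseline_label = "baseline",
                                harmonics = table_harmonics(measurements),
                                alpha = 0.05) {
  stopifnot(is.data.frame(measurements))
  conds <- unique(measurements$condition)
  if (!(baseline_label %in% conds))
    stop(sprintf("baseline group '%s' is missing from the measurement table",
                 baseline_label), call. = FALSE)
  others <- setdiff(conds, baseline_label)
  rows <- list()
  for (k in harmonics) {
    gcol <- paste0("g", k); scol <- paste0("s", k)
    if (!all(c(gcol, scol) %in% names(measurements)))
      stop(sprintf("measurement table lacks harmonic %d columns", k),
           call. = FALSE)
    base <- as.matrix(
      measurements[measurements$condition == baseline_label, c(gcol, scol)])
    for (cond in others) {
      grp <- as.matrix(
        measurements[measurements$condition == cond, c(gcol, scol)])
      if (nrow(grp) < 3L)
        stop(sprintf("condition '%s' has fewer than 3 measurements", cond),
             call. = FALSE)
      ht <- hotelling_t2(grp, base)
      el <- std_dev_ellipse(grp)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, harmonic = as.integer(k),
        n_condition = nrow(grp), n_baseline = nrow(base),
        t2 = ht$t2, f_stat = ht$f_stat, df1 = ht$df[1], df2 = ht$df[2],
        p_value = ht$p_value, significant = ht$p_value < alpha,
        center_g = unname(el$center[1]), center_s = unname(el$center[2]),
        semi_major = el$semi_major, semi_minor = el$semi_minor,
        angle = el$angle, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
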