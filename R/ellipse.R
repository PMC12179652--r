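#' Isoprobability (confidence) ellipse of a bivariate Gaussian
#'
#' The contour of equal density enclosing a stated probability mass: points on
#' the ellipse have squared Mahalanobis distance `k^2` equal to the chi-square
#' quantile with 2 degrees of freedom at the level (`k^2 = -2 log(1 - level)`).
#' Axes lie along the covariance eigenvectors with semi-axis lengths
#' `sqrt(eigenvalue) * k`.  The centre — the mean length and width — is the
#' most probable value of the variable pair.
#'
#' @param mean numeric length-2 centre (e.g. mean length and width, um).
#' @param covariance 2x2 symmetric positive-definite covariance matrix (um^2).
#' @param level probability level in (0, 1); spore and pileipellis size distributions are conventionally drawn at 0.68.
#' @return an object of class `iso_ellipse` with fields `center`,
#'   `semi_axes` (major, minor), `angle` (radians of the major axis from the
#'   length axis), `level`, `k2`, `covariance`.
#' @examples
#' isoprobability_ellipse(c(11.6, 5.0), diag(c(0.36, 0.04)))
#' @export
isoprobability_ellipse <- function(mean, covariance, level = 0.68) {
  stopifnot(length(mean) == 2L, is.matrix(covariance),
            all(dim(covariance) == 2L))
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, abs(covariance)))
    stop("covariance must be symmetric")
  ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  if (any(ev$values <= .Machine$double.eps * max(abs(ev$values), 1)))
    stop("covariance must be positive definite (singular matrix supplied)")
  k2 <- stats::qchisq(level, df = 2)
  angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  if (angle > pi / 2) angle <- angle - pi        # eigenvector sign is arbitrary
  if (angle <= -pi / 2) angle <- angle + pi
  structure(list(center = as.numeric(mean),
                 semi_axes = sqrt(ev$values * k2),
                 angle = angle,
                 level = level, k2 = k2,
                 covariance = covariance,
                 cov_inv = solve(covariance)),
            class = "iso_ellipse")
}

#' Fit an isoprobability ellipse to measurements
#'
#' Builds the ellipse from the sample mean and covariance (n-1 denominator) of
#' (length, width) observations.  With `use_collection_means = TRUE` the
#' ellipse is fitted to the per-collection mean points instead of the raw
#' structures — the mode used when comparing the spore-size distributions of
#' species across collections.
#'
#' @param ms a [measurement_set()] or a two-column matrix/data frame of
#'   (length, width) points.
#' @param level probability level in (0, 1).
#' @param use_collection_means fit to collection means rather than raw points
#'   (requires a `measurement_set`).
#' @return an `iso_ellipse`.
#' @export
fit_isoprobability_ellipse <- function(ms, level = 0.68,
                                       use_collection_means = FALSE) {
  pts <- as_points(ms, use_collection_means)
  if (nrow(pts) < 3L) stop("need at least 3 points to fit an ellipse")
  isoprobability_ellipse(colMeans(pts), stats::cov(pts), level)
}

as_points <- function(x, use_collection_means = FALSE) {
  if (inherits(x, "measurement_set") ||
      (is.data.frame(x) && all(c("length_um", "width_um") %in% names(x)))) {
    if (use_collection_means) {
      coll <- as.character(x$collection)
      cbind(as.numeric(tapply(x$length_um, coll, mean)),
            as.numeric(tapply(x$width_um, coll, mean)))
    } else cbind(x$length_um, x$width_um)
  } else {
    pts <- as.matrix(x)
    stopifnot(ncol(pts) == 2L)
    pts
  }
}

#' Which points fall inside an isoprobability ellipse
#'
#' @param points two-column matrix/data frame of (length, width) points.
#' @param ellipse an [isoprobability_ellipse()].
#' @return logical vector; boundary points count as inside.
#' @export
in_ellipse <- function(points, ellipse) {
  stopifnot(inherits(ellipse, "iso_ellipse"))
  pts <- as_points(points)
  d <- sweep(pts, 2, ellipse$center)
  md2 <- rowSums((d %*% ellipse$cov_inv) * d)
  md2 <= ellipse$k2 + 1e-12
}

#' Empirical coverage of an isoprobability ellipse
#'
#' Percentage of points with squared Mahalanobis distance at most `k^2`
#' (boundary inclusive).  For points truly drawn from the Gaussian the
#' ellipse was built from, the coverage converges to the nominal level.
#'
#' @inheritParams in_ellipse
#' @return coverage percentage in \[0, 100\].
#' @export
ellipse_coverage <- function(points, ellipse) {
  pts <- as_points(points)
  if (nrow(pts) < 1L) stop("at least one point required")
  100 * mean(in_ellipse(pts, ellipse))
}

#' @export
print.iso_ellipse <- function(x, ...) {
  cat(sprintf(
    "isoprobability ellipse (level %.2f): centre (%.2f, %.2f), semi-axes %.3f x %.3f, angle %.1f deg\n",
    x$level, x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    180 * x$angle / pi))
  invisible(x)
}
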