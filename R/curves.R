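#' Backbone curve objects
#'
#' A `backbone_curve` is an ordered sequence of 3D point samples along a
#' protein backbone (or any open space curve), together with its parameter
#' grid on \[0, 1\] and a free-text label. It is the input representation for
#' all elastic shape computations: curves are resampled to a common grid,
#' rescaled to unit length, and converted to square-root velocity functions
#' before comparison.
#'
#' @param points numeric matrix with one row per sample and 3 columns (x, y, z).
#' @param params numeric vector of strictly increasing parameter values in
#'   \[0, 1\], one per row of `points`. Defaults to a uniform grid on \[0, 1\].
#' @param label free-text identifier (e.g. "1MP6_A" or "helix30").
#'
#' @return An object of class `backbone_curve`: a list with elements
#'   `points` (n x 3 matrix), `params` (length n), `label`.
#' @export
#' @examples
#' b <- backbone_curve(cbind(0:4, 0, 0))
#' curve_length(b)
backbone_curve <- function(points, params = NULL, label = "curve") {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("'points' must be a numeric matrix with 3 columns")
  n <- nrow(points)
  if (n < 2L) stop("a backbone curve needs at least 2 points")
  if (!all(is.finite(points))) stop("curve coordinates must be finite")
  if (is.null(params)) params <- seq(0, 1, length.out = n)
  params <- as.numeric(params)
  if (length(params) != n) stop("'params' length must match number of points")
  if (any(diff(params) <= 0)) stop("'params' must be strictly increasing")
  if (curve_length_points(points) <= 0)
    stop("curve has zero length (all points identical)")
  structure(list(points = points, params = params, label = as.character(label)),
            class = "backbone_curve")
}

#' @export
print.backbone_curve <- function(x, ...) {
  cat(sprintf("<backbone_curve '%s': %d points, length %.4f>\n",
              x$label, nrow(x$points), curve_length(x)))
  invisible(x)
}

curve_length_points <- function(points) {
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Polyline length of a curve
#'
#' Sum of Euclidean distances between consecutive sample points.
#'
#' @param curve a [backbone_curve()].
#' @return scalar length (same units as the coordinates).
#' @export
curve_length <- function(curve) {
  stopifnot(inherits(curve, "backbone_curve"))
  curve_length_points(curve$points)
}

#' Resample a curve at uniformly spaced parameters
#'
#' Piecewise-linear interpolation of each coordinate against the curve's
#' parameter grid, evaluated at `m` uniformly spaced parameters on \[0, 1\]
#' (endpoints included). The first and last points are preserved exactly.
#'
#' @param curve a [backbone_curve()].
#' @param m number of output samples (>= 2).
#' @return a [backbone_curve()] with `m` points on a uniform grid.
#' @export
resample_curve <- function(curve, m) {
  stopifnot(inherits(curve, "backbone_curve"))
  if (!is.numeric(m) || length(m) != 1L || m < 2)
    stop("'m' must be a single integer >= 2")
  m <- as.integer(m)
  tin <- curve$params
  tout <- seq(min(tin), max(tin), length.out = m)
  pts <- vapply(1:3, function(d)
    approx(tin, curve$points[, d], xout = tout, rule = 2)$y,
    numeric(m))
  backbone_curve(pts, seq(0, 1, length.out = m), curve$label)
}

#' Rescale a curve to unit polyline length
#'
#' Multiplies the coordinates by the reciprocal of the polyline length so
#' that the output has length exactly 1; the shape is unchanged up to
#' uniform scaling. Idempotent.
#'
#' @param curve a [backbone_curve()].
#' @return a [backbone_curve()] of unit length.
#' @export
rescale_to_unit_length <- function(curve) {
  stopifnot(inherits(curve, "backbone_curve"))
  len <- curve_length(curve)
  if (len <= 0) stop("cannot rescale a zero-length curve")
  backbone_curve(curve$points / len, curve$params, curve$label)
}

#' Resample a curve uniformly by arclength
#'
#' Places `m` samples at equal arclength spacing along the polyline,
#' interpolating linearly between the input points, and returns them on a
#' uniform parameter grid. Because the output depends only on the polyline
#' trace, any two parameterizations of the same polyline resample to the
#' identical curve: this canonicalization makes shape comparisons exactly
#' invariant to the input parameterization.
#'
#' @param curve a [backbone_curve()].
#' @param m number of output samples (>= 2).
#' @return a [backbone_curve()] with `m` points at constant speed.
#' @export
resample_by_arclength <- function(curve, m) {
  stopifnot(inherits(curve, "backbone_curve"))
  if (!is.numeric(m) || length(m) != 1L || m < 2)
    stop("'m' must be a single integer >= 2")
  m <- as.integer(m)
  curve <- collapse_repeated_points(curve)
  seg <- sqrt(rowSums(diff(curve$points)^2))
  s <- c(0, cumsum(seg))
  s <- s / s[length(s)]
  sout <- seq(0, 1, length.out = m)
  pts <- vapply(1:3, function(d)
    approx(s, curve$points[, d], xout = sout, rule = 2)$y,
    numeric(m))
  backbone_curve(pts, seq(0, 1, length.out = m), curve$label)
}

#' Drop exactly repeated consecutive points
#'
#' Repeated consecutive samples carry zero velocity and are collapsed before
#' SRVF conversion so the parameter grid stays strictly informative.
#'
#' @param curve a [backbone_curve()].
#' @return a [backbone_curve()] without zero-length segments.
#' @export
collapse_repeated_points <- function(curve) {
  stopifnot(inherits(curve, "backbone_curve"))
  d <- sqrt(rowSums(diff(curve$points)^2))
  keep <- c(TRUE, d > 0)
  if (all(keep)) return(curve)
  backbone_curve(curve$points[keep, , drop = FALSE],
                 curve$params[keep], curve$label)
}

# Apply a rigid rotation (3x3, det +1) to every point.
rotate_curve <- function(curve, R) {
  backbone_curve(curve$points %*% t(R), curve$params, curve$label)
}
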