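#' Square-root velocity functions
#'
#' The SRVF of a curve beta is q(t) = beta'(t) / sqrt(|beta'(t)|), sampled
#' here on a uniform grid over \[0, 1\]. The representation is translation
#' invariant, and the squared L2 norm of q equals the curve length, so after
#' rescaling to unit length (or projecting onto the preshape sphere) curves
#' are compared modulo translation and scale. All inner products and norms
#' use trapezoidal quadrature on the common grid.
#'
#' @param values numeric m x 3 matrix of SRVF samples on the uniform grid.
#' @param label free-text identifier carried along from the source curve.
#' @return an object of class `srvf`.
#' @export
srvf <- function(values, label = "srvf") {
  values <- as.matrix(values)
  if (!is.numeric(values) || ncol(values) != 3L || nrow(values) < 2L)
    stop("'values' must be a numeric matrix with 3 columns and >= 2 rows")
  if (!all(is.finite(values))) stop("SRVF values must be finite")
  structure(list(values = values, label = as.character(label)), class = "srvf")
}

#' @export
print.srvf <- function(x, ...) {
  cat(sprintf("<srvf '%s': grid %d, L2 norm %.6f>\n",
              x$label, nrow(x$values), l2_norm(x)))
  invisible(x)
}

# trapezoidal quadrature weights on the uniform grid with m points
trapz_weights <- function(m) {
  h <- 1 / (m - 1)
  c(h / 2, rep(h, m - 2L), h / 2)
}

#' L2 inner product of two SRVFs
#'
#' Trapezoidal approximation of the integral of <q1(t), q2(t)> over \[0, 1\].
#' Both functions must be sampled on the same grid.
#'
#' @param q1,q2 [srvf()] objects with equal grid size.
#' @return scalar inner product.
#' @export
l2_inner <- function(q1, q2) {
  stopifnot(inherits(q1, "srvf"), inherits(q2, "srvf"))
  m <- nrow(q1$values)
  if (nrow(q2$values) != m) stop("SRVF grid sizes differ; resample first")
  sum(trapz_weights(m) * rowSums(q1$values * q2$values))
}

#' L2 norm of an SRVF
#'
#' @param q an [srvf()].
#' @return scalar norm (sqrt of the squared-norm quadrature).
#' @export
l2_norm <- function(q) sqrt(max(0, l2_inner(q, q)))

#' Convert a curve to its square-root velocity function
#'
#' The derivative is estimated by finite differences on the uniform grid
#' (central in the interior, one-sided at the endpoints). Where the speed is
#' exactly zero the SRVF is set to the zero vector (its limiting value).
#' Curves on non-uniform grids are resampled to a uniform grid of the same
#' size first.
#'
#' @param curve a [backbone_curve()].
#' @param grid_size optional output grid size; default keeps the curve's
#'   number of samples.
#' @return an [srvf()].
#' @export
curve_to_srvf <- function(curve, grid_size = NULL) {
  stopifnot(inherits(curve, "backbone_curve"))
  curve <- collapse_repeated_points(curve)
  m <- if (is.null(grid_size)) nrow(curve$points) else as.integer(grid_size)
  curve <- resample_curve(curve, m)
  p <- curve$points
  h <- 1 / (m - 1)
  v <- if (m == 2L) {
    rbind((p[2, ] - p[1, ]) / h, (p[2, ] - p[1, ]) / h)
  } else {
    rbind((p[2, ] - p[1, ]) / h,
          (p[3:m, , drop = FALSE] - p[1:(m - 2), , drop = FALSE]) / (2 * h),
          (p[m, ] - p[m - 1, ]) / h)
  }
  speed <- sqrt(rowSums(v^2))
  q <- v
  nz <- speed > 0
  q[nz, ] <- v[nz, , drop = FALSE] / sqrt(speed[nz])
  q[!nz, ] <- 0
  srvf(q, curve$label)
}

#' Reconstruct a curve from its SRVF by integration
#'
#' Inverts the SRVF map up to translation: beta(t) = origin +
#' integral of q(s) |q(s)| ds, evaluated with the cumulative trapezoid rule.
#'
#' @param q an [srvf()].
#' @param origin 3-vector giving the reconstructed curve's starting point.
#' @return a [backbone_curve()] on the same uniform grid.
#' @export
srvf_to_curve <- function(q, origin = c(0, 0, 0)) {
  stopifnot(inherits(q, "srvf"), length(origin) == 3L)
  m <- nrow(q$values)
  h <- 1 / (m - 1)
  integrand <- q$values * sqrt(rowSums(q$values^2))
  pts <- matrix(0, m, 3)
  for (d in 1:3) {
    f <- integrand[, d]
    pts[, d] <- c(0, cumsum((f[-m] + f[-1]) / 2 * h))
  }
  pts <- sweep(pts, 2, origin, "+")
  # guard: an all-zero SRVF integrates to a single point; keep a valid curve
  if (curve_length_points(pts) <= 0)
    pts[, 1] <- pts[, 1] + seq(0, 1e-12, length.out = m)
  backbone_curve(pts, seq(0, 1, length.out = m), q$label)
}

#' Project an SRVF onto the preshape sphere
#'
#' Divides by the L2 norm so the result has unit norm; the preshape sphere
#' is the set of SRVFs of unit-length curves, i.e. curves modulo translation
#' and scale.
#'
#' @param q an [srvf()] with positive norm.
#' @return an [srvf()] with `l2_norm(q) == 1` to within 1e-10.
#' @export
project_to_preshape <- function(q) {
  stopifnot(inherits(q, "srvf"))
  nrm <- l2_norm(q)
  if (nrm <= 0) stop("cannot project the zero function onto the preshape sphere")
  srvf(q$values / nrm, q$label)
}

#' Resample an SRVF onto a different uniform grid size
#'
#' Linear interpolation per coordinate. Comparisons require a common grid,
#' so pairs are brought to the same size before alignment.
#'
#' @param q an [srvf()].
#' @param m target grid size.
#' @return an [srvf()] with `m` samples.
#' @export
resample_srvf <- function(q, m) {
  stopifnot(inherits(q, "srvf"), m >= 2)
  m0 <- nrow(q$values)
  if (m0 == m) return(q)
  t0 <- seq(0, 1, length.out = m0)
  t1 <- seq(0, 1, length.out = m)
  vals <- vapply(1:3, function(d) approx(t0, q$values[, d], xout = t1)$y,
                 numeric(m))
  srvf(vals, q$label)
}

# standard preprocessing: collapse repeats, canonicalize to uniform
# arclength sampling, rescale to unit length, SRVF, project to the
# preshape sphere. Arclength canonicalization makes the result independent
# of the input parameterization (which the elastic matching optimizes over
# anyway) and gives exact reparameterization invariance of distances.
prepare_srvf <- function(curve, grid_size = 100L) {
  curve <- collapse_repeated_points(curve)
  curve <- resample_by_arclength(curve, grid_size)
  curve <- rescale_to_unit_length(curve)
  project_to_preshape(curve_to_srvf(curve))
}
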