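#' Log map on the preshape sphere
#'
#' Maps a unit-norm SRVF q into the tangent space at the mean mu:
#' v = (theta / sin theta) (q - cos(theta) mu) with theta = arccos<mu, q>.
#' The image satisfies <v, mu> = 0 and |v| = theta, i.e. v is the initial
#' direction (scaled by arc length) of the great circle from mu to q.
#'
#' @param mu unit-norm [srvf()] (base point).
#' @param q unit-norm [srvf()] with theta < pi.
#' @return an [srvf()]-shaped tangent vector (m x 3 values, same grid).
#' @export
log_map <- function(mu, q) {
  stopifnot(inherits(mu, "srvf"), inherits(q, "srvf"))
  ip <- max(-1, min(1, l2_inner(mu, q)))
  theta <- acos(ip)
  if (theta >= pi - 1e-4)
    stop("log map undefined for (near-)antipodal points (theta = pi)")
  if (theta < 1e-12) return(srvf(matrix(0, nrow(mu$values), 3), q$label))
  srvf((theta / sin(theta)) * (q$values - ip * mu$values), q$label)
}

#' Exponential map on the preshape sphere
#'
#' Inverse of [log_map()]: exp_mu(v) = cos(|v|) mu + sin(|v|) v / |v|,
#' returning mu itself for |v| = 0. The output has unit norm.
#'
#' @param mu unit-norm [srvf()] (base point).
#' @param v tangent vector at mu (an [srvf()]-shaped object).
#' @return a unit-norm [srvf()].
#' @export
exp_map <- function(mu, v) {
  stopifnot(inherits(mu, "srvf"), inherits(v, "srvf"))
  nv <- l2_norm(v)
  if (nv < 1e-14) return(srvf(mu$values, mu$label))
  srvf(cos(nv) * mu$values + sin(nv) * v$values / nv, mu$label)
}

#' Karcher mean of a set of shapes
#'
#' The mean shape minimizes the sum of squared geodesic distances to the
#' given SRVFs. It is found by iterated tangent-space averaging: every
#' shape is aligned (rotation + reparameterization) to the current mean,
#' mapped to the tangent space with [log_map()], and the mean is moved
#' along the average tangent direction with [exp_map()] using step size
#' `step` (halved whenever the objective would increase). Iteration stops
#' when the average tangent norm falls below `tol`.
#'
#' @param shapes list of unit-norm [srvf()] objects on matched grids.
#' @param tol convergence threshold on the mean tangent norm.
#' @param max_iter maximum gradient iterations.
#' @param step initial gradient step size.
#' @param K maximum DP lattice slope used in the per-shape alignments.
#' @return object of class `shape_mean`: list with `mu` (unit-norm
#'   [srvf()]), `sum_sq_dist`, `iterations`, `converged`, `objective_trace`,
#'   and `aligned` (the input shapes aligned to the final mean).
#' @export
karcher_mean <- function(shapes, tol = 1e-5, max_iter = 50L, step = 0.5, K = 4L) {
  if (length(shapes) < 1L) stop("need at least one shape")
  stopifnot(all(vapply(shapes, inherits, logical(1), "srvf")))
  m <- nrow(shapes[[1]]$values)
  if (!all(vapply(shapes, function(q) nrow(q$values), integer(1)) == m))
    stop("all shapes must share one grid size")
  n <- length(shapes)
  if (n == 1L) {
    mu <- project_to_preshape(shapes[[1]])
    return(structure(list(mu = mu, sum_sq_dist = 0, iterations = 0L,
                          converged = TRUE, objective_trace = 0,
                          aligned = list(mu)),
                     class = "shape_mean"))
  }

  shapes <- lapply(shapes, project_to_preshape)
  # initialize: extrinsic average of shapes aligned to the first one
  aligned0 <- c(shapes[1],
                lapply(shapes[-1], function(q) align(shapes[[1]], q, K = K)$q2_star))
  avg <- Reduce(`+`, lapply(aligned0, `[[`, "values")) / n
  mu <- srvf(avg, "karcher_mean")
  if (l2_norm(mu) < 1e-10) stop("degenerate initialization: shapes cancel out")
  mu <- project_to_preshape(mu)

  eps <- step
  obj_trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  it <- 0L
  aligned <- shapes
  while (it < max_iter) {
    it <- it + 1L
    aligned <- lapply(shapes, function(q) align(mu, q, K = K)$q2_star)
    thetas <- vapply(aligned, function(qs)
      acos(max(-1, min(1, l2_inner(mu, qs)))), numeric(1))
    obj <- sum(thetas^2)
    if (obj > obj_prev + 1e-10) {
      # overshoot: retreat and take a smaller step
      eps <- eps / 2
      mu <- exp_map(mu_prev, srvf(eps * vbar_prev$values, "step"))
      if (eps < 1e-6) { obj_trace <- c(obj_trace, obj_prev); break }
      next
    }
    obj_trace <- c(obj_trace, obj)
    vs <- lapply(aligned, function(qs) log_map(mu, qs))
    vbar <- srvf(Reduce(`+`, lapply(vs, `[[`, "values")) / n, "vbar")
    if (l2_norm(vbar) < tol) { converged <- TRUE; obj_prev <- obj; break }
    mu_prev <- mu
    vbar_prev <- vbar
    obj_prev <- obj
    mu <- exp_map(mu, srvf(eps * vbar$values, "step"))
  }
  if (!converged)
    warning("Karcher mean did not converge within max_iter; returning best iterate")
  structure(list(mu = mu,
                 sum_sq_dist = obj_trace[length(obj_trace)],
                 iterations = it,
                 converged = converged,
                 objective_trace = obj_trace,
                 aligned = aligned),
            class = "shape_mean")
}

#' @export
print.shape_mean <- function(x, ...) {
  cat(sprintf("<shape_mean: grid %d, sum of squared distances %.5f, %d iteration(s)%s>\n",
              nrow(x$mu$values), x$sum_sq_dist, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# flatten a tangent vector into 3m coordinates scaled by sqrt(quadrature
# weights), so Euclidean inner products in the flat space equal L2 inner
# products on the grid
flatten_tangent <- function(v) {
  w <- sqrt(trapz_weights(nrow(v)))
  as.numeric(v * w)
}

unflatten_tangent <- function(x, m) {
  w <- sqrt(trapz_weights(m))
  matrix(x, m, 3) / w
}

#' Tangent-space covariance of a shape population
#'
#' Aligns each shape to the Karcher mean, maps it to the tangent space at
#' the mean, and computes the sample covariance of the (quadrature-
#' weighted) flattened tangent vectors. Its singular value decomposition
#' K = U Sigma U^t yields the principal directions of shape variation; the
#' k = min(n - 1, 3m) directions with singular value above 1e-12 are kept.
#'
#' @param mean a `shape_mean` from [karcher_mean()] (or a unit-norm
#'   [srvf()] used directly as the mean).
#' @param shapes list of >= 2 unit-norm [srvf()] objects.
#' @param align_shapes if `TRUE` (default) each shape is re-aligned to the
#'   mean before the log map; set `FALSE` when the shapes are already
#'   aligned.
#' @param n_residues optional residue count of the underlying backbone,
#'   used by [residue_variance()] to pool grid points per residue.
#' @return object of class `shape_distribution`: list with `mean`
#'   (unit-norm [srvf()]), `U` (list of tangent matrices), `sigma`
#'   (decreasing variances), `k`, `n`, `grid_size`, `n_residues`.
#' @export
shape_covariance <- function(mean, shapes, align_shapes = TRUE,
                             n_residues = NULL) {
  mu <- if (inherits(mean, "shape_mean")) mean$mu else mean
  stopifnot(inherits(mu, "srvf"))
  n <- length(shapes)
  if (n < 2L) stop("need at least 2 shapes for a covariance")
  stopifnot(all(vapply(shapes, inherits, logical(1), "srvf")))
  m <- nrow(mu$values)
  if (align_shapes)
    shapes <- lapply(shapes, function(q) align(mu, project_to_preshape(q))$q2_star)
  V <- t(vapply(shapes, function(q) flatten_tangent(log_map(mu, q)$values),
                numeric(3 * m)))
  Kmat <- cov(V)
  eig <- eigen(Kmat, symmetric = TRUE)
  sigma <- pmax(eig$values, 0)
  kmax <- min(n - 1L, 3L * m)
  keep <- which(sigma > 1e-12)
  keep <- keep[keep <= kmax]
  U <- lapply(keep, function(j) unflatten_tangent(eig$vectors[, j], m))
  structure(list(mean = mu,
                 U = U,
                 sigma = sigma[keep],
                 k = length(keep),
                 n = n,
                 grid_size = m,
                 n_residues = if (is.null(n_residues)) m else as.integer(n_residues),
                 trace_K = sum(diag(Kmat))),
            class = "shape_distribution")
}

#' @export
print.shape_distribution <- function(x, ...) {
  cat(sprintf("<shape_distribution: n = %d shapes, grid %d, k = %d component(s), top sigma %.3g>\n",
              x$n, x$grid_size, x$k, if (x$k > 0) x$sigma[1] else NA_real_))
  invisible(x)
}

#' Sample random shapes from a Gaussian-type shape distribution
#'
#' Draws independent standard normal coefficients z_1..z_k, forms the
#' tangent direction v = sum_j z_j sqrt(sigma_j) U_j, and maps it to the
#' sphere with [exp_map()]. With k = 0 (degenerate distribution) every
#' sample equals the mean. Reproducible for a fixed seed.
#'
#' @param dist a `shape_distribution` from [shape_covariance()].
#' @param count number of samples.
#' @param seed integer seed for the draws.
#' @return list of unit-norm [srvf()] objects.
#' @export
sample_shapes <- function(dist, count, seed) {
  stopifnot(inherits(dist, "shape_distribution"), count >= 1)
  set.seed(as.integer(seed))
  m <- dist$grid_size
  lapply(seq_len(count), function(s) {
    if (dist$k == 0L) return(srvf(dist$mean$values, sprintf("sample_%d", s)))
    z <- rnorm(dist$k)
    v <- matrix(0, m, 3)
    for (j in seq_len(dist$k))
      v <- v + z[j] * sqrt(dist$sigma[j]) * dist$U[[j]]
    out <- exp_map(dist$mean, srvf(v, "v"))
    srvf(out$values, sprintf("sample_%d", s))
  })
}

#' Sweep a principal direction of shape variation
#'
#' Reconstructs the shapes exp_mu(t sqrt(sigma_i) U_i) for a range of t
#' (by convention t in \[-2, 2\]), visualizing the variability captured by
#' the i-th principal direction. t = 0 reproduces the mean shape.
#'
#' @param dist a `shape_distribution`.
#' @param component principal-direction index (1 = largest variance).
#' @param t_values numeric multiples of the standard deviation.
#' @return list of [backbone_curve()] objects, one per `t` value.
#' @export
principal_sweep <- function(dist, component = 1L,
                            t_values = seq(-2, 2, length.out = 9)) {
  stopifnot(inherits(dist, "shape_distribution"))
  if (component < 1 || component > dist$k)
    stop(sprintf("component must be in 1..%d", dist$k))
  lapply(t_values, function(t) {
    v <- srvf(t * sqrt(dist$sigma[component]) * dist$U[[component]], "v")
    cur <- srvf_to_curve(exp_map(dist$mean, v))
    cur$label <- sprintf("sweep_c%d_t%+.2f", component, t)
    cur
  })
}

# map grid-point index to residue index (each residue owns the samples
# nearest to it in parameter)
grid_to_residue <- function(m, n_residues) {
  t0 <- seq(0, 1, length.out = m)
  pmin(n_residues, floor(t0 * n_residues) + 1L)
}

#' Per-residue positional variance of a shape distribution
#'
#' Samples `n_samples` random structures, reconstructs their curves,
#' rigidly superposes each onto the mean curve (common centroid plus the
#' rotation from SRVF alignment to the mean), and reports the mean squared
#' deviation of each residue's position from the mean curve, pooled over
#' the grid points belonging to that residue. Large values flag flexible
#' regions (e.g. a disordered terminus).
#'
#' @param dist a `shape_distribution`.
#' @param n_samples number of random structures (>= 2; the reference
#'   analysis used 10).
#' @param seed integer seed.
#' @return numeric vector of length `dist$n_residues`.
#' @export
residue_variance <- function(dist, n_samples = 10L, seed = 1L) {
  stopifnot(inherits(dist, "shape_distribution"))
  if (n_samples < 2L) stop("need at least 2 samples for a variance")
  samples <- sample_shapes(dist, n_samples, seed)
  mean_curve <- srvf_to_curve(dist$mean)
  mp <- scale(mean_curve$points, center = TRUE, scale = FALSE)
  m <- dist$grid_size
  sqdev <- matrix(0, n_samples, m)
  for (s in seq_len(n_samples)) {
    q <- samples[[s]]
    O <- optimal_rotation(dist$mean, q)
    cur <- srvf_to_curve(rotate_srvf(q, O))
    cp <- scale(cur$points, center = TRUE, scale = FALSE)
    sqdev[s, ] <- rowSums((cp - mp)^2)
  }
  per_point <- colMeans(sqdev)
  res_of <- grid_to_residue(m, dist$n_residues)
  as.numeric(tapply(per_point, res_of, mean))
}

#' Gaussian tangent density of a shape under a shape distribution
#'
#' Maps q to the tangent space at the mean, projects onto the k retained
#' principal directions, and evaluates the k-dimensional Gaussian density
#' with variances sigma_j (product of independent normals). The component
#' of the tangent vector orthogonal to the retained span is ignored; a
#' nonzero coordinate on a zero-variance direction yields density 0 with a
#' warning. This is a density on the tangent space, not a normalized
#' probability over shapes.
#'
#' @param dist a `shape_distribution`.
#' @param q unit-norm [srvf()].
#' @param align_shape if `TRUE` (default) align q to the mean first.
#' @return scalar density value.
#' @export
tangent_density <- function(dist, q, align_shape = TRUE) {
  stopifnot(inherits(dist, "shape_distribution"), inherits(q, "srvf"))
  if (align_shape) q <- align(dist$mean, project_to_preshape(q))$q2_star
  v <- log_map(dist$mean, q)
  if (dist$k == 0L) {
    if (l2_norm(v) > 1e-8) { warning("shape outside a degenerate distribution; density 0"); return(0) }
    return(1)
  }
  coords <- vapply(seq_len(dist$k),
                   function(j) l2_inner(v, srvf(dist$U[[j]], "u")),
                   numeric(1))
  dens <- prod(dnorm(coords, mean = 0, sd = sqrt(dist$sigma)))
  dens
}
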