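test_that("log and exp maps are mutually inverse with the right norms", {
  set.seed(3)
  mu <- prep(make_curve("helix", 25), 60)
  for (rep in 1:5) {
    q <- prep(make_curve("random_smooth", 22, seed = rep), 60)
    th <- theta_between(mu, q)
    v <- log_map(mu, q)
    expect_equal(l2_norm(v), th, tolerance = 1e-8)
    expect_lt(abs(l2_inner(v, mu)), 1e-8)        # tangency
    back <- exp_map(mu, v)
    expect_equal(back$values, q$values, tolerance = 1e-8)
    expect_equal(l2_norm(back), 1, tolerance = 1e-8)
    expect_equal(theta_between(mu, exp_map(mu, v)), l2_norm(v), tolerance = 1e-8)
  }
  expect_equal(log_map(mu, mu)$values, matrix(0, 60, 3))
  expect_equal(exp_map(mu, srvf(matrix(0, 60, 3)))$values, mu$values)
  expect_error(log_map(mu, srvf(-mu$values)), "antipodal")
})

test_that("Karcher mean: single shape, two-shape geodesic midpoint, monotone objective", {
  q1 <- prep(make_curve("helix", 25), 80)
  km1 <- karcher_mean(list(q1))
  expect_equal(km1$mu$values, q1$values, tolerance = 1e-10)
  expect_equal(km1$sum_sq_dist, 0)

  q2 <- prep(make_curve("bent_helix", 25, bend_angle = pi / 6), 80)
  km2 <- karcher_mean(list(q1, q2))
  expect_true(all(diff(km2$objective_trace) <= 1e-6))
  # the two-shape mean lies at the tau = 0.5 point of the aligned geodesic
  res <- align(q1, q2)
  mid <- geodesic_path(q1, res$q2_star, steps = 3)[[2]]
  expect_lt(theta_between(km2$mu, mid), 1e-3)
  expect_error(karcher_mean(list()), "at least one")
})

test_that("covariance recovers a rank-1 construction and the trace identity", {
  set.seed(8)
  mu <- prep(make_curve("helix", 25), 60)
  u <- esaprot:::tangent_basis_at(mu, 1)[[1]]
  coef <- rnorm(12, sd = 0.1)
  shapes <- lapply(coef, function(ci) exp_map(mu, srvf(ci * u$values)))
  dist <- shape_covariance(mu, shapes, align_shapes = FALSE)
  expect_s3_class(dist, "shape_distribution")
  expect_true(all(diff(dist$sigma) <= 0))
  u1 <- srvf(dist$U[[1]])
  expect_gt(abs(l2_inner(u1, u)), 0.99)
  if (dist$k > 1) expect_lt(dist$sigma[2] / dist$sigma[1], 1e-6)
  # orthonormality and tangency of the retained directions
  for (j in seq_len(dist$k)) {
    expect_equal(l2_norm(srvf(dist$U[[j]])), 1, tolerance = 1e-6)
    expect_lt(abs(l2_inner(srvf(dist$U[[j]]), mu)), 1e-6)
  }
  # trace(K) identity against the tangent scatter
  vs <- lapply(shapes, function(q) log_map(mu, q)$values)
  vbar <- Reduce(`+`, vs) / length(vs)
  scatter <- sum(vapply(vs, function(v)
    l2_inner(srvf(v - vbar), srvf(v - vbar)), numeric(1))) / (length(vs) - 1)
  expect_equal(dist$trace_K, scatter, tolerance = 1e-8)
  # identical shapes: no variance, k = 0
  same <- lapply(1:4, function(i) mu)
  expect_equal(shape_covariance(mu, same, align_shapes = FALSE)$k, 0L)
  expect_error(shape_covariance(mu, list(mu)), "at least 2")
})

test_that("sampling is seeded, degenerate for zero variance, and covariance-consistent", {
  mu <- prep(make_curve("helix", 25), 60)
  basis <- esaprot:::tangent_basis_at(mu, 2)
  dist <- structure(list(mean = mu,
                         U = lapply(basis, `[[`, "values"),
                         sigma = c(0.02, 0.005), k = 2L, n = 10L,
                         grid_size = 60L, n_residues = 25L, trace_K = 0.025),
                    class = "shape_distribution")
  s1 <- sample_shapes(dist, 5, seed = 7)
  s2 <- sample_shapes(dist, 5, seed = 7)
  for (k in 1:5) expect_equal(s1[[k]]$values, s2[[k]]$values)
  degen <- dist; degen$k <- 0L; degen$U <- list(); degen$sigma <- numeric(0)
  for (q in sample_shapes(degen, 3, seed = 1))
    expect_equal(q$values, mu$values)
  # Monte-Carlo consistency of the tangent covariance (moderate n here)
  s <- sample_shapes(dist, 2000, seed = 21)
  V <- t(vapply(s, function(q) esaprot:::flatten_tangent(log_map(mu, q)$values),
                numeric(180)))
  Kemp <- cov(V)
  w <- sqrt(esaprot:::trapz_weights(60))
  Kmod <- matrix(0, 180, 180)
  for (j in 1:2) {
    uf <- as.numeric(basis[[j]]$values * w)
    Kmod <- Kmod + dist$sigma[j] * tcrossprod(uf)
  }
  expect_lt(norm(Kemp - Kmod, "F") / norm(Kmod, "F"), 0.1)
})

test_that("principal sweeps are symmetric about the mean with arc length |t| sqrt(sigma)", {
  mu <- prep(make_curve("helix", 20), 50)
  basis <- esaprot:::tangent_basis_at(mu, 1)
  dist <- structure(list(mean = mu, U = list(basis[[1]]$values),
                         sigma = 0.04, k = 1L, n = 10L,
                         grid_size = 50L, n_residues = 20L, trace_K = 0.04),
                    class = "shape_distribution")
  sw <- principal_sweep(dist, 1, t_values = c(-2, -1, 0, 1, 2))
  expect_length(sw, 5L)
  mean_curve <- srvf_to_curve(mu)
  expect_equal(sw[[3]]$points, mean_curve$points, tolerance = 1e-12)
  # in SRVF space the sweep is exactly symmetric with arc length |t| sqrt(sigma)
  for (t in c(-2, -1, 1, 2)) {
    qt <- exp_map(mu, srvf(t * sqrt(dist$sigma[1]) * basis[[1]]$values))
    expect_equal(theta_between(mu, qt), abs(t) * sqrt(dist$sigma[1]),
                 tolerance = 1e-8)
  }
  # reconstructed curves: distances from the mean grow with |t| and the
  # +/-t pair stays roughly balanced (reconstruction re-differentiates a
  # rough polyline, so only approximate symmetry can be expected)
  th_of <- function(cv) theta_between(mu, project_to_preshape(curve_to_srvf(cv)))
  ths <- vapply(sw, th_of, numeric(1))
  expect_true(all(diff(ths[1:3]) < 0))
  expect_true(all(diff(ths[3:5]) > 0))
  expect_lt(abs(ths[5] - ths[1]), 0.06)
  expect_lt(abs(ths[4] - ths[2]), 0.06)
  expect_error(principal_sweep(dist, 5), "component")
})

test_that("residue variance is zero for degenerate ensembles and localizes tail noise", {
  mu <- prep(make_curve("helix", 25), 75)
  degen <- structure(list(mean = mu, U = list(), sigma = numeric(0), k = 0L,
                          n = 10L, grid_size = 75L, n_residues = 25L,
                          trace_K = 0),
                     class = "shape_distribution")
  rv0 <- residue_variance(degen, n_samples = 4, seed = 2)
  expect_length(rv0, 25L)
  expect_lt(max(rv0), 1e-20)
  expect_error(residue_variance(degen, n_samples = 1), "at least 2")
  # noise confined to the last 20% of the curve shows up only there
  a <- make_curve("helix", 30)
  ens <- make_ensemble(a, n = 20, noise_sd = 0.15, noise_support = c(0.8, 1),
                       grid_size = 90, seed = 5)
  km <- suppressWarnings(karcher_mean(ens$shapes, max_iter = 30))
  dist <- shape_covariance(km, km$aligned, align_shapes = FALSE, n_residues = 30)
  rv <- residue_variance(dist, n_samples = 10, seed = 6)
  expect_length(rv, 30L)
  tail_idx <- 25:30
  expect_gt(mean(rv[tail_idx]) / mean(rv[-c(tail_idx)]), 5)
})

test_that("tangent density prefers high-variance directions and decays with |t|", {
  mu <- prep(make_curve("helix", 25), 60)
  basis <- esaprot:::tangent_basis_at(mu, 2)
  dist <- structure(list(mean = mu,
                         U = lapply(basis, `[[`, "values"),
                         sigma = c(0.04, 0.001), k = 2L, n = 10L,
                         grid_size = 60L, n_residues = 25L, trace_K = 0.041),
                    class = "shape_distribution")
  # equidistant shapes along the two directions: higher density along U1
  d <- 0.1
  q_top <- exp_map(mu, srvf(d * basis[[1]]$values))
  q_low <- exp_map(mu, srvf(d * basis[[2]]$values))
  expect_equal(theta_between(mu, q_top), theta_between(mu, q_low), tolerance = 1e-8)
  expect_gt(tangent_density(dist, q_top, align_shape = FALSE),
            tangent_density(dist, q_low, align_shape = FALSE))
  # monotone decay along a single direction
  dens <- vapply(c(0, 0.05, 0.1, 0.2), function(t)
    tangent_density(dist, exp_map(mu, srvf(t * basis[[1]]$values)),
                    align_shape = FALSE), numeric(1))
  expect_true(all(diff(dens) < 0))
  # k = 1 standard normal at the mean evaluates to 1/sqrt(2 pi)
  d1 <- dist; d1$k <- 1L; d1$U <- dist$U[1]; d1$sigma <- 1
  expect_equal(tangent_density(d1, mu, align_shape = FALSE), 1 / sqrt(2 * pi))
})

test_that("ensembles with zero noise are exact copies; generation is seeded", {
  a <- make_curve("bent_helix", 24, bend_angle = pi / 5)
  ens0 <- make_ensemble(a, n = 4, noise_sd = 0, grid_size = 50, seed = 3)
  for (q in ens0$shapes)
    expect_equal(q$values, ens0$truth$mu0$values, tolerance = 1e-12)
  e1 <- make_ensemble(a, n = 3, noise_sd = 0.1, grid_size = 50, seed = 11)
  e2 <- make_ensemble(a, n = 3, noise_sd = 0.1, grid_size = 50, seed = 11)
  for (k in 1:3) expect_equal(e1$shapes[[k]]$values, e2$shapes[[k]]$values)
  expect_error(make_ensemble(a, 3, noise_support = c(0.5, 0.2)), "interval")
})
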