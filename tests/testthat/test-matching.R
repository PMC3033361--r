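test_that("optimal_rotation recovers a known rotation and stays in SO(3)", {
  q1 <- prep(make_curve("helix_turn_helix", 30), 80)  # non-planar
  expect_equal(optimal_rotation(q1, q1), diag(3), tolerance = 1e-8)
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  q2 <- srvf(q1$values %*% R)   # rows q1 R = t(R) applied pointwise
  O <- optimal_rotation(q1, q2)
  expect_equal(O, R, tolerance = 1e-8)
  expect_equal(det(O), 1, tolerance = 1e-10)
  expect_equal(t(O) %*% O, diag(3), tolerance = 1e-10)
  # degenerate input still yields a proper rotation
  Od <- optimal_rotation(q1, srvf(matrix(0, 80, 3)))
  expect_equal(det(Od), 1, tolerance = 1e-10)
})

test_that("apply_reparam matches the closed form and preserves norm", {
  m <- 201
  t0 <- seq(0, 1, length.out = m)
  q <- srvf(matrix(c(1, 0, 0), m, 3, byrow = TRUE))
  g <- reparam(t0^2)
  out <- apply_reparam(q, g)
  interior <- 3:(m - 2)
  expect_lt(max(abs(out$values[interior, 1] - sqrt(2 * t0[interior]))), 1e-3)
  # identity leaves q unchanged
  qh <- prep(make_curve("helix", 25), m)
  expect_equal(apply_reparam(qh, reparam(t0))$values, qh$values, tolerance = 1e-10)
  # norm preservation for a smooth gamma on a smoothly sampled curve
  hc <- helix_constants()
  omega <- 2 * pi / hc$residues_per_turn
  ms <- 401
  s <- seq(0, 12, length.out = ms)
  smooth <- backbone_curve(cbind(hc$radius * cos(omega * s),
                                 hc$radius * sin(omega * s), hc$rise * s))
  qs <- project_to_preshape(curve_to_srvf(rescale_to_unit_length(smooth)))
  ts <- seq(0, 1, length.out = ms)
  gs <- reparam((exp(1.5 * ts) - 1) / (exp(1.5) - 1))
  expect_equal(l2_norm(apply_reparam(qs, gs)), l2_norm(qs), tolerance = 1e-3)
  expect_error(reparam(c(0, 0.5, 0.4, 1)), "nondecreasing")
  expect_error(reparam(c(0.2, 0.5, 1)), "gamma\\(0\\)")
})

test_that("dynamic programming equals exhaustive path enumeration on small grids", {
  set.seed(42)
  for (rep in 1:4) {
    m <- sample(8:10, 1)
    q1 <- prep(make_curve("random_smooth", 12, seed = rep), m)
    q2 <- prep(make_curve("random_smooth", 12, seed = rep + 100), m)
    g <- optimal_reparam_dp(q1, q2)
    expect_equal(attr(g, "cost"), oracle_min_path_cost(q1$values, q2$values),
                 tolerance = 1e-12)
  }
  expect_error(optimal_reparam_dp(prep(make_curve("helix", 10), 2),
                                  prep(make_curve("helix", 10), 2)),
               "grid too small")
})

test_that("DP returns the identity for identical inputs and recovers warps", {
  m <- 100
  t0 <- seq(0, 1, length.out = m)
  q1 <- prep(make_curve("bent_helix", 30, bend_angle = pi / 5), m)
  g_id <- optimal_reparam_dp(q1, q1)
  expect_lt(max(abs(as.numeric(g_id) - t0)), 2 / (m - 1))
  # construct-and-recover: q2 = gamma0 action on q1, smooth gamma0
  g0 <- (exp(2 * t0) - 1) / (exp(2) - 1)
  q2 <- project_to_preshape(apply_reparam(q1, reparam(g0)))
  g <- optimal_reparam_dp(q1, q2)
  # recovered gamma composed with gamma0 is the identity: g0(gamma(t)) = t
  comp <- approx(t0, g0, xout = as.numeric(g))$y
  expect_lt(max(abs(comp - t0)), 2 * 4 / (m - 1))
  # optimal cost never exceeds the identity cost
  id_cost <- l2_inner(srvf(q1$values - q2$values), srvf(q1$values - q2$values))
  expect_lte(attr(g, "cost"), id_cost + 1e-12)
})

test_that("alignment is exact on identical shapes and monotone in cost", {
  q1 <- prep(make_curve("helix_turn_helix", 28), 90)
  res <- align(q1, q1)
  expect_s3_class(res, "geodesic_result")
  expect_lt(res$theta, 1e-6)
  q2 <- prep(make_curve("hairpin", 28), 90)
  res2 <- align(q1, q2)
  expect_true(all(diff(res2$cost_trace) <= 1e-12))
  expect_equal(res2$theta,
               acos(max(-1, min(1, l2_inner(q1, res2$q2_star)))),
               tolerance = 1e-12)
  expect_equal(det(res2$rotation), 1, tolerance = 1e-8)
})

test_that("geodesic distance is invariant to all shape-preserving transformations", {
  a <- make_curve("bent_helix", 30, bend_angle = pi / 4)
  R <- rotation_matrix(c(2, -1, 1), 0.9)
  moved <- backbone_curve(a$points %*% t(R) + matrix(c(5, -3, 8), 30, 3, byrow = TRUE),
                          label = "moved")
  expect_lt(geodesic_distance(a, moved), 0.02)
  scaled <- backbone_curve(0.37 * a$points, label = "scaled")
  expect_lt(geodesic_distance(a, scaled), 0.02)
  warped <- backbone_curve(a$points, params = seq(0, 1, length.out = 30)^1.7,
                           label = "warped")
  expect_lt(geodesic_distance(a, warped), 0.02)
  combo <- backbone_curve(2.2 * a$points %*% t(R) + 3,
                          params = sqrt(seq(0, 1, length.out = 30)),
                          label = "combo")
  expect_lt(geodesic_distance(a, combo), 0.02)
  expect_lt(geodesic_distance(a, a), 1e-6)
})

test_that("geodesic_path traverses the great circle at constant speed", {
  m <- 60
  q1 <- prep(make_curve("helix", 25), m)
  res <- align(q1, prep(make_curve("bent_helix", 25, bend_angle = pi / 3), m))
  path <- geodesic_path(q1, res$q2_star, steps = 7)
  expect_length(path, 7L)
  expect_equal(path[[1]]$values, q1$values, tolerance = 1e-12)
  expect_equal(path[[7]]$values, res$q2_star$values, tolerance = 1e-12)
  theta <- res$theta
  for (k in 1:7) {
    expect_equal(l2_norm(path[[k]]), 1, tolerance = 1e-6)
    expect_equal(theta_between(q1, path[[k]]), (k - 1) / 6 * theta,
                 tolerance = 1e-6)
  }
  # closed-form midpoint of two orthogonal constant SRVFs
  e1 <- srvf(matrix(c(1, 0, 0), m, 3, byrow = TRUE))
  e2 <- srvf(matrix(c(0, 1, 0), m, 3, byrow = TRUE))
  mid <- geodesic_path(e1, e2, steps = 3)[[2]]
  expect_equal(mid$values, matrix(c(1, 1, 0) / sqrt(2), m, 3, byrow = TRUE),
               tolerance = 1e-10)
  expect_error(geodesic_path(e1, srvf(-e1$values), steps = 3), "antipodal")
})
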