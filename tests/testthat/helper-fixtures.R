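# Shared test helpers: PDB text fixtures built in code, an independent
# brute-force elastic-matching oracle, and small geometry utilities.

# write a PDB text file with full N/CA/C backbones; `models` is a list of
# n_res x 9 matrices (N, CA, C coordinates per residue); optionally drop
# specific atoms (list of c(model, residue, atom_index 1:3))
write_backbone_pdb <- function(path, models, chain = "A", resno = NULL,
                               drop = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  atom_names <- c("N", "CA", "C")
  elements <- c("N", "C", "C")
  for (mi in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", mi), con)
    coords <- models[[mi]]
    n_res <- nrow(coords)
    rn <- if (is.null(resno)) seq_len(n_res) else resno
    serial <- 0L
    for (r in seq_len(n_res)) {
      for (a in 1:3) {
        if (!is.null(drop) &&
            any(vapply(drop, function(d)
              all(d == c(mi, r, a)), logical(1)))) next
        serial <- serial + 1L
        xyz <- coords[r, (3 * (a - 1) + 1):(3 * a)]
        writeLines(sprintf(
          "ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, atom_names[a], chain, rn[r], xyz[1], xyz[2], xyz[3],
          elements[a]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# n_res x 9 matrix of roughly backbone-like N/CA/C positions along a helix
helix_backbone_coords <- function(n_res, shift = 0) {
  ca <- esaprot::make_curve("helix", max(n_res, 4))$points[seq_len(n_res), , drop = FALSE]
  ca <- ca + shift
  nn <- ca + matrix(c(-0.5, 0.4, -0.6), n_res, 3, byrow = TRUE)
  cc <- ca + matrix(c(0.6, -0.3, 0.5), n_res, 3, byrow = TRUE)
  cbind(nn, ca, cc)
}

rotation_matrix <- function(axis = c(0, 0, 1), angle = 0.7) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# --- independent oracle for the elastic matching lattice problem --------
# prices one lattice edge with its own R arithmetic (same cost definition
# as the matcher, implemented independently)
oracle_edge_cost <- function(Q1, Q2, i0, i1, j0, j1) {
  m <- nrow(Q1)
  h <- 1 / (m - 1)
  slope <- (j1 - j0) / (i1 - i0)
  sq <- sqrt(slope)
  tot <- 0
  for (p in i0:i1) {
    g <- (j0 + slope * (p - i0)) * h
    x <- g * (m - 1)
    k <- floor(x)
    if (k >= m - 1) k <- m - 2
    fr <- x - k
    q2g <- (1 - fr) * Q2[k + 1, ] + fr * Q2[k + 2, ]
    f <- sum((Q1[p + 1, ] - sq * q2g)^2)
    w <- if (p == i0 || p == i1) 0.5 else 1
    tot <- tot + w * f
  }
  tot * h
}

oracle_steps <- function(K = 4L) {
  gg <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }
  out <- NULL
  for (di in 1:K) for (dj in 1:K)
    if (gg(di, dj) == 1) out <- rbind(out, c(di, dj))
  out
}

# exhaustive depth-first enumeration over all monotone lattice paths
oracle_min_path_cost <- function(Q1, Q2, K = 4L) {
  m <- nrow(Q1)
  steps <- oracle_steps(K)
  best <- Inf
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == m - 1 && j == m - 1) { best <<- min(best, acc); return(invisible()) }
    for (s in seq_len(nrow(steps))) {
      i1 <- i + steps[s, 1]; j1 <- j + steps[s, 2]
      if (i1 <= m - 1 && j1 <= m - 1)
        rec(i1, j1, acc + oracle_edge_cost(Q1, Q2, i, i1, j, j1))
    }
  }
  rec(0L, 0L, 0)
  best
}

prep <- function(curve, m) esaprot:::prepare_srvf(curve, m)

theta_between <- function(qa, qb) acos(max(-1, min(1, l2_inner(qa, qb))))

# the 20-curve synthetic suite used by the metric-axiom checks
metric_suite_curves <- function(seed = 1L) {
  set.seed(seed)
  curves <- list(
    make_curve("helix", 25),
    make_curve("helix", 35),
    make_curve("bent_helix", 30, bend_angle = pi / 6),
    make_curve("bent_helix", 30, bend_angle = pi / 3),
    make_curve("bent_helix", 24, bend_angle = pi / 2),
    make_curve("helix_turn_helix", 30),
    make_curve("helix_turn_helix", 36, bend_angle = pi / 4),
    make_curve("hairpin", 24),
    make_curve("hairpin", 32)
  )
  for (s in 1:11)
    curves <- c(curves, list(make_curve("random_smooth", 20 + s, seed = seed + s)))
  curves
}
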