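# Shared fixtures and independent oracles (kept deliberately separate from
# the package implementations they check).

# a small hand-written PDB fixture: n CA atoms on a helix, one with an
# insertion code
write_fixture_pdb <- function(path, n = 12) {
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, i, if (i == 3) "A" else " ",
            10 * cos(i / 2), 10 * sin(i / 2), 1.5 * i, 1.00, 20.00)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

random_cloud <- function(n, spread = 20) {
  matrix(runif(3 * n, -spread, spread), ncol = 3)
}

# O(n^2) brute-force bad-overlap count, independent of the package's
# spatial-hash implementation
brute_overlaps <- function(a, b, threshold = 0.4,
                           radii = c(C = 1.70, N = 1.55, O = 1.52,
                                     S = 1.80, P = 1.80)) {
  ra <- radii[toupper(a$atoms$element)]
  rb <- radii[toupper(b$atoms$element)]
  xa <- coords(a); xb <- coords(b)
  count <- 0L
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (ra[i] + rb[j] - d >= threshold - 1e-9) count <- count + 1L
  }
  count
}

# independent rigid-superposition minimizer: quaternion grid search plus
# Nelder-Mead refinement on the rotation vector; never touches the SVD path
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotvec_to_mat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  u <- v / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

grid_minimize_rmsd <- function(ref, mov, n_grid = 4000) {
  A <- sweep(mov, 2, colMeans(mov))
  B <- sweep(ref, 2, colMeans(ref))
  score_mat <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  best <- Inf; best_q <- c(1, 0, 0, 0)
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  for (i in seq_len(n_grid)) {
    s <- score_mat(quat_to_mat(qs[i, ]))
    if (s < best) { best <- s; best_q <- qs[i, ] }
  }
  R0 <- quat_to_mat(best_q)
  # rotation vector of R0 for the local refinement start
  ang <- acos(max(-1, min(1, (sum(diag(R0)) - 1) / 2)))
  v0 <- if (ang < 1e-9) c(0, 0, 0) else
    ang / (2 * sin(ang)) * c(R0[3, 2] - R0[2, 3], R0[1, 3] - R0[3, 1],
                             R0[2, 1] - R0[1, 2])
  opt <- optim(v0, function(v) score_mat(rotvec_to_mat(v)),
               method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  opt$value
}
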