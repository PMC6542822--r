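# Cyclic groups, symmetry expansion, Euler conventions and the head-tail
# orientation-mismatch statistics.

test_that("cyclic groups have the right order, closure and identity", {
  g1 <- cyclic_group(1)
  expect_length(g1$ops, 1)
  expect_equal(g1$ops[[1]]$matrix, diag(3))

  g12 <- cyclic_group(12)
  expect_length(g12$ops, 12)
  acc <- diag(3)
  for (i in 1:12) acc <- g12$ops[[2]]$matrix %*% acc
  expect_lt(max(abs(acc - diag(3))), 1e-9)

  set.seed(8)
  ax <- rnorm(3)
  g5 <- cyclic_group(5, ax)
  mats <- lapply(g5$ops, `[[`, "matrix")
  for (a in mats) for (b in mats) {
    prod_in_group <- any(vapply(mats, function(m)
      max(abs(m - a %*% b)) < 1e-6, TRUE))
    expect_true(prod_in_group)
  }
  expect_error(cyclic_group(0), "positive")
})

test_that("expand_assembly places copies exactly and rigidly", {
  m1 <- make_model(matrix(c(10, 0, 0), 1))
  e <- expand_assembly(m1, cyclic_group(4))
  expect_equal(coords(e),
               rbind(c(10, 0, 0), c(0, 10, 0), c(-10, 0, 0), c(0, -10, 0)),
               tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(3)
  mono <- make_model(random_cloud(100, 15), chain = "A", resno = 1:100)
  c1 <- expand_assembly(mono, cyclic_group(1))
  expect_equal(coords(c1), coords(mono))

  g12 <- cyclic_group(12)
  big <- expand_assembly(mono, g12)
  expect_equal(n_atoms(big), 1200)
  # applying the inverse operator to copy k recovers copy 0 exactly, and
  # all intra-copy pairwise distances are preserved (rigidity)
  d0 <- dist(coords(mono))
  for (k in c(2, 7, 12)) {
    idx <- ((k - 1) * 100 + 1):(k * 100)
    xk <- coords(big)[idx, ]
    back <- xk %*% g12$ops[[k]]$matrix  # R^-1 = t(R), applied as x %*% R
    expect_lt(max(abs(back - coords(mono))), 1e-9)
    expect_lt(max(abs(dist(xk) - d0)), 1e-9)
  }
})

test_that("euler conversion follows intrinsic ZYZ and round-trips", {
  expect_equal(euler_to_matrix(euler_triple(0, 0, 0))$matrix, diag(3))
  # alt = 90 about y maps z onto x
  R <- euler_to_matrix(euler_triple(90, 0, 0))$matrix
  expect_equal(as.numeric(R %*% c(0, 0, 1)), c(1, 0, 0), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:1000) {
    e <- euler_triple(runif(1, 0.01, 179.99), runif(1, 0, 360),
                      runif(1, 0, 360))
    e2 <- matrix_to_euler(euler_to_matrix(e))
    expect_lt(max(abs(e2$alt - e$alt), ang_diff(e2$az, e$az),
                  ang_diff(e2$phi, e$phi)), 1e-6)
  }
  # gimbal lock: phi absorbs az
  g <- matrix_to_euler(euler_to_matrix(euler_triple(0, 25, 30)))
  expect_equal(g$az, 0)
  expect_equal(g$phi, 55, tolerance = 1e-9)
})

test_that("equivalent orientations form the azimuth progression and match the operators", {
  e <- euler_triple(40, 10, 70)
  eq1 <- equivalent_orientations(e, 1)
  expect_equal(eq1[[1]], e)
  eq12 <- equivalent_orientations(e, 12)
  expect_equal(vapply(eq12, `[[`, 1, "az"), seq(10, 340, by = 30))
  expect_true(all(vapply(eq12, `[[`, 1, "alt") == 40))
  # operator-level: R_equiv(k) composed with the inverse group rotation
  # recovers the input rotation
  g <- cyclic_group(12)
  R0 <- euler_to_matrix(e)$matrix
  for (k in 1:12) {
    Rk <- euler_to_matrix(eq12[[k]])$matrix
    expect_lt(max(abs(t(g$ops[[k]]$matrix) %*% Rk - R0)), 1e-9)
  }
})

test_that("min_azimuth_diff is bounded, brute-force exact and equivalence-invariant", {
  expect_equal(min_azimuth_diff(list(az = 123), list(az = 123), 12), 0)
  expect_equal(min_azimuth_diff(list(az = 0), list(az = 45), 12), 15)

  set.seed(17)
  diffs <- numeric(10000)
  for (i in seq_along(diffs)) {
    h <- runif(1, 0, 360); t <- runif(1, 0, 360)
    v <- min_azimuth_diff(list(az = h), list(az = t), 12)
    bf <- min(vapply(0:11, function(k) ang_diff(h, t + k * 30), 1))
    expect_identical(v, bf)
    diffs[i] <- v
  }
  expect_true(all(diffs <= 15 + 1e-12))
  # independent head/tail azimuths give a uniform mismatch distribution
  expect_gt(suppressWarnings(ks.test(diffs, "punif", 0, 15)$p.value), 0.01)
  # invariance under replacing the tail by any equivalent
  e <- euler_triple(30, 77, 5)
  base <- min_azimuth_diff(list(az = 200), e, 12)
  for (eq in equivalent_orientations(e, 12))
    expect_equal(min_azimuth_diff(list(az = 200), eq, 12), base,
                 tolerance = 1e-9)
})

test_that("pair filtering applies the 5-degree alt/phi screen exactly", {
  pairs <- data.frame(particle_id = c("a", "b", "c", "d"),
                      alt_head = c(90, 90, 90, 90), az_head = 0,
                      phi_head = c(10, 10, 10, 358),
                      alt_tail = c(90, 96, 94, 90), az_tail = 0,
                      phi_tail = c(10, 10, 16, 2))
  kept <- filter_orientation_pairs(pairs)
  # b: delta alt = 6 discarded; c: delta phi = 6 discarded; d: wrapped
  # delta phi = 4 retained
  expect_equal(kept$particle_id, c("a", "d"))

  os <- make_orientation_set(42, n_particles = 1000, outlier_fraction = 0.3)
  expect_equal(nrow(filter_orientation_pairs(os$pairs)), 700)
})

test_that("mismatch summary classifies fixed, free and oscillating regimes", {
  same <- data.frame(particle_id = "x", alt_head = 90, az_head = 100,
                     phi_head = 0, alt_tail = 90, az_tail = 100, phi_tail = 0)
  ms <- mismatch_summary(same[rep(1, 50), ], 12)
  expect_equal(ms$concentration, 1)
  expect_equal(ms$classification, "fixed")
  expect_error(mismatch_summary(same[0, ], 12), "no orientation pairs")

  fixed <- make_orientation_set(9, mode = "fixed", jitter_sd = 1)
  expect_equal(mismatch_summary(filter_orientation_pairs(fixed$pairs),
                                12)$classification, "fixed")
  free <- make_orientation_set(9, mode = "free")
  expect_equal(mismatch_summary(filter_orientation_pairs(free$pairs),
                                12)$classification, "non-fixed")

  osc <- make_orientation_set(9, mode = "oscillating", half_width = 3)
  md <- mismatch_summary(filter_orientation_pairs(osc$pairs), 12)$min_diffs
  expect_gt(mean(md < 6), 0.99)
})
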