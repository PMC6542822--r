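# Rasterization, FSC, map-model correlation, pixel calibration and local
# symmetry averaging.

test_that("rasterization is local, symmetric and linear in atomic number", {
  empty <- structure_model(data.frame(
    atom_name = character(0), residue_name = character(0),
    residue_number = integer(0), chain_id = character(0),
    element = character(0), x = numeric(0), y = numeric(0), z = numeric(0)))
  g0 <- rasterize(empty, 1, c(8, 8, 8))
  expect_true(all(g0$values == 0))

  # single carbon at the grid centre: maximum at the centre voxel,
  # spherically symmetric within voxelization
  gc <- rasterize(make_model(matrix(0, 1, 3)), 1, c(17, 17, 17))
  expect_equal(which.max(gc$values),
               which(array(seq_len(17^3), c(17, 17, 17)) ==
                       ((9 - 1) * 17 + 9 - 1) * 17 + 9))
  expect_equal(gc$values[9 + 4, 9, 9], gc$values[9, 9 - 4, 9],
               tolerance = 1e-12)

  # integrated density proportional to the sum of atomic numbers: the
  # ratio integral / sum(Z) is the same constant for every model (1e-6
  # relative) and matches the analytic Gaussian integral (2 pi)^(3/2)
  set.seed(41)
  ratios <- vapply(1:20, function(i) {
    n <- sample(3:12, 1)
    els <- sample(c("C", "N", "O", "S", "P"), n, replace = TRUE)
    m <- make_model(random_cloud(n, 6), element = els)
    g <- rasterize(m, 1, c(40, 40, 40))
    sum(g$values) / sum(c(C = 6, N = 7, O = 8, S = 16, P = 15)[els])
  }, numeric(1))
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-6)
  expect_equal(ratios[1], (2 * pi)^1.5, tolerance = 1e-4)

  expect_error(rasterize(make_model(matrix(c(100, 0, 0), 1)), 1, c(8, 8, 8)),
               "outside the grid")
})

test_that("FSC is exact on identical, negated and null inputs", {
  set.seed(42)
  m <- make_model(random_cloud(20, 10))
  g <- rasterize(m, 1, c(32, 32, 32))
  self <- fsc(g, g)
  expect_lt(max(abs(self$correlations - 1)), 1e-9)
  expect_true(all(diff(self$shell_freqs) > 0))
  neg <- fsc(g, density_grid(-g$values, g$voxel, g$origin))
  expect_lt(max(abs(neg$correlations + 1)), 1e-9)
  # scale invariance
  sc <- fsc(g, density_grid(3.7 * g$values, g$voxel, g$origin))
  expect_lt(max(abs(sc$correlations - 1)), 1e-9)

  # independent white noise: per-shell |FSC| within the null bound for
  # well-populated shells
  n1 <- density_grid(array(rnorm(32^3), c(32, 32, 32)), 1)
  n2 <- density_grid(array(rnorm(32^3), c(32, 32, 32)), 1)
  null <- fsc(n1, n2)
  big <- null$shell_voxels >= 100
  expect_true(all(abs(null$correlations[big]) <
                    3 / sqrt(null$shell_voxels[big])))
  expect_error(fsc(g, density_grid(array(0, c(16, 16, 16)), 1)), "dimensions")
})

test_that("FSC resolution threshold is found by interpolation", {
  set.seed(43)
  m <- make_model(random_cloud(25, 10))
  g <- rasterize(m, 1, c(32, 32, 32))
  noisy <- density_grid(g$values + 0.8 * sd(g$values) *
                          array(rnorm(32^3), c(32, 32, 32)), 1, g$origin)
  f <- fsc(g, noisy)
  if (!is.na(f$resolution_at_threshold)) {
    expect_gt(f$resolution_at_threshold, 2)   # cannot beat Nyquist (2 A)
    expect_gt(f$correlations[1], 0.9)          # low shells agree
  }
  expect_true(is.na(fsc(g, g)$resolution_at_threshold))
})

test_that("map-model CC is 1 for a perfect map, ~0 off density, monotone in noise", {
  set.seed(44)
  m <- make_model(random_cloud(20, 8))
  g <- rasterize(m, 1.2, c(36, 36, 36))
  expect_equal(map_model_cc(g, m), 1, tolerance = 1e-6)

  off <- set_coords(m, coords(m) + 300)
  expect_lt(abs(map_model_cc(g, off, clip = TRUE)), 0.05)

  ccs <- vapply(c(0.2, 0.8, 2, 5), function(s) {
    noisy <- density_grid(g$values + s * sd(g$values) *
                            array(rnorm(36^3), c(36, 36, 36)), 1.2, g$origin)
    map_model_cc(noisy, m)
  }, numeric(1))
  expect_true(all(ccs > 0 & ccs < 1))
  expect_true(all(diff(ccs) < 0))
})

test_that("pixel calibration recovers planted pixel sizes", {
  # self-consistency: correctly labelled map calibrates to its own label
  nm0 <- make_noisy_map(7, true_pixel = 1.30, nominal_pixel = 1.30,
                        noise_sd = 0)
  cal0 <- calibrate_pixel(nm0$grid, nm0$model, 1.25, 1.40, 31)
  expect_false(cal0$boundary)
  expect_lt(abs(cal0$calibrated_pixel - 1.30), 0.002)

  # the headline case: rasterized at 1.30, mislabelled 1.32, noisy
  nm <- make_noisy_map(8)
  cal <- calibrate_pixel(nm$grid, nm$model, 1.25, 1.40, 31)
  expect_lt(abs(cal$calibrated_pixel - 1.300), 0.005)
  # concavity of the CC curve near its maximum: quadratic fit residual
  # small relative to the CC range
  imax <- which.max(cal$cc_values)
  idx <- (imax - 2):(imax + 2)
  pred <- cal$fit_coefficients[1] + cal$fit_coefficients[2] *
    cal$pixel_values[idx] + cal$fit_coefficients[3] * cal$pixel_values[idx]^2
  expect_lt(max(abs(pred - cal$cc_values[idx])),
            0.05 * diff(range(cal$cc_values)))

  # recovery across seeded fixtures: |error| <= 0.5% of the true pixel
  for (s in 1:10) {
    nms <- make_noisy_map(100 + s, true_pixel = 1.28 + 0.004 * s,
                          nominal_pixel = 1.32, dims = c(40, 40, 40))
    cals <- calibrate_pixel(nms$grid, nms$model, 1.22, 1.42, 41)
    expect_lt(abs(cals$calibrated_pixel - nms$truth$true_pixel),
              0.005 * nms$truth$true_pixel)
  }

  # a maximum at the sweep edge is flagged, not extrapolated
  nmb <- make_noisy_map(9, true_pixel = 1.24, nominal_pixel = 1.32)
  expect_warning(calb <- calibrate_pixel(nmb$grid, nmb$model, 1.30, 1.40, 21),
                 "boundary")
  expect_true(calb$boundary)
})

test_that("local symmetry averaging symmetrizes, fixes symmetric input and is idempotent", {
  set.seed(46)
  blob <- make_model(random_cloud(6, 8) + matrix(c(12, 0, 0), 6, 3,
                                                 byrow = TRUE))
  g <- rasterize(blob, 1, c(56, 56, 56))
  avg <- local_symmetry_average(g, 5, mask_radius = 24)
  # output is C5-invariant within interpolation error
  rot <- local_symmetry_average(avg, 5, mask_radius = 24)
  expect_lt(sqrt(mean((rot$values - avg$values)^2)) / max(avg$values), 0.01)

  # C5-symmetric input is a fixed point within interpolation error
  c5 <- expand_assembly(blob, cyclic_group(5))
  gs <- rasterize(c5, 1, c(56, 56, 56))
  avg_s <- local_symmetry_average(gs, 5, mask_radius = 24)
  expect_lt(sqrt(mean((avg_s$values - gs$values)^2)) / max(gs$values), 0.02)

  # n = 2 on a density antisymmetric under the half-turn cancels
  pos <- make_model(matrix(c(8, 0, 0), 1))
  gp <- rasterize(pos, 1, c(48, 48, 48))
  ga <- density_grid(gp$values - aperm(gp$values[48:1, 48:1, ], c(1, 2, 3)),
                     1, gp$origin)
  cancelled <- local_symmetry_average(ga, 2, mask_radius = 20)
  ctr <- 15:34
  expect_lt(max(abs(cancelled$values[ctr, ctr, ctr])),
            1e-6 * max(abs(ga$values)))

  expect_error(local_symmetry_average(g, 5, mask_radius = 1000), "outside")
})
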