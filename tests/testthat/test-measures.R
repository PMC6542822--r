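# Radial profiles, salt bridges and buried surface area.

test_that("radial profile matches the analytic ring and is rotation-invariant", {
  az <- seq(0, 330, by = 30) * pi / 180
  ring <- make_model(cbind(40 * cos(az), 40 * sin(az), 0))
  p <- radial_profile(ring, slab_thickness = 5)
  slab <- p[p$n_atoms > 0, ]
  expect_equal(nrow(slab), 1)
  expect_equal(slab$outer_diameter, 2 * (40 + 1.70))  # 83.4
  expect_equal(slab$inner_diameter, 2 * (40 - 1.70))  # 76.6

  R <- rotation_about_axis(c(0, 0, 1), 17)
  p2 <- radial_profile(set_coords(ring, coords(ring) %*% t(R)),
                       slab_thickness = 5)
  expect_equal(p2[p2$n_atoms > 0, ]$outer_radius, slab$outer_radius,
               tolerance = 1e-9)

  # a filled cylinder has no axial channel
  set.seed(51)
  fill <- make_model(cbind(runif(500, -1.4, 1.4), runif(500, -1.4, 1.4),
                           runif(500, 0, 40)))
  pf <- radial_profile(fill, slab_thickness = 5)
  expect_true(all(pf$inner_radius[pf$n_atoms > 10] == 0))
})

test_that("funnel diameters and planted state changes are recovered", {
  fn <- make_funnel()
  pa <- radial_profile(fn$state_a)
  pb <- radial_profile(fn$state_b)
  stem_a <- pa[pa$z_lo >= 45 & pa$z_hi <= 175 & pa$n_atoms > 0, ]
  expect_lt(max(abs(stem_a$outer_diameter - 55)), 0.5)
  expect_lt(max(abs(stem_a$inner_diameter - 32)), 0.5)
  # planted +8 A narrow-end radial expansion reads as +16 A in diameter
  narrow <- which(pa$z_lo >= 175 & pa$n_atoms > 0 & pa$outer_diameter > 50)
  dd <- pb$outer_diameter[narrow] - pa$outer_diameter[narrow]
  expect_lt(max(abs(dd - 16)), 0.5)
  # per-range RMSD localizes the planted stem contraction
  anames <- sprintf("C%02d", 1:24)
  rr <- rmsd_ranges(fn$state_a, fn$state_b,
                    list(as.numeric(fn$truth$mouth_range),
                         as.numeric(fn$truth$upper_stem_range),
                         as.numeric(fn$truth$narrow_range)),
                    atom = anames, fit_on = "none")
  expect_equal(rr$per_range$rmsd[1], 0, tolerance = 1e-12)
  expect_equal(rr$per_range$rmsd[2], fn$truth$contract_stem,
               tolerance = 1e-9)
  expect_equal(rr$per_range$rmsd[3], fn$truth$expand_narrow,
               tolerance = 1e-9)
  # zero-change copy: all deltas vanish
  fz <- make_funnel(expand_narrow = 0, contract_stem = 0)
  expect_equal(coords(fz$state_a), coords(fz$state_b))
})

test_that("salt bridges follow the donor/acceptor atom rules and cutoff", {
  lys <- make_model(matrix(0, 1, 3), atom_name = "NZ", residue_name = "LYS",
                    element = "N", resno = 10)
  glu <- function(d) make_model(matrix(c(d, 0, 0), 1), atom_name = "OE1",
                                residue_name = "GLU", element = "O",
                                chain = "B", resno = 99)
  expect_equal(nrow(salt_bridges(lys, glu(3.5))), 1)
  expect_equal(nrow(salt_bridges(lys, glu(4.5))), 0)
  # direction-agnostic: acidic partner may sit in either model
  expect_equal(nrow(salt_bridges(glu(3.5), lys)), 1)
  # backbone-like atoms never count
  gly_o <- make_model(matrix(c(3, 0, 0), 1), atom_name = "O",
                      residue_name = "GLY", element = "O")
  expect_equal(nrow(salt_bridges(lys, gly_o)), 0)
  # His only with the flag
  his <- make_model(matrix(c(3, 0, 0), 1), atom_name = "ND1",
                    residue_name = "HIS", element = "N", chain = "B")
  asp <- make_model(matrix(0, 1, 3), atom_name = "OD2",
                    residue_name = "ASP", element = "O")
  expect_equal(nrow(salt_bridges(asp, his)), 0)
  expect_equal(nrow(salt_bridges(asp, his, include_his = TRUE)), 1)
})

test_that("salt bridges equal a brute-force all-pair scan on random fixtures", {
  set.seed(52)
  res_pool <- list(
    list(res = "LYS", at = "NZ", el = "N", basic = TRUE),
    list(res = "ARG", at = "NH1", el = "N", basic = TRUE),
    list(res = "ASP", at = "OD1", el = "O", basic = FALSE),
    list(res = "GLU", at = "OE2", el = "O", basic = FALSE),
    list(res = "GLY", at = "CA", el = "C", basic = NA))
  for (rep in 1:50) {
    pick <- function(n, chain) {
      sel <- sample(res_pool, n, replace = TRUE)
      structure_model(data.frame(
        atom_name = vapply(sel, `[[`, "", "at"),
        residue_name = vapply(sel, `[[`, "", "res"),
        residue_number = seq_len(n),
        chain_id = chain,
        element = vapply(sel, `[[`, "", "el"),
        x = runif(n, -8, 8), y = runif(n, -8, 8), z = runif(n, -8, 8)))
    }
    a <- pick(12, "A"); b <- pick(12, "B")
    found <- salt_bridges(a, b)
    # brute force over all atom pairs
    n_expected <- 0L
    for (i in seq_len(12)) for (j in seq_len(12)) {
      ri <- a$atoms[i, ]; rj <- b$atoms[j, ]
      basic_i <- ri$residue_name %in% c("LYS", "ARG")
      acidic_j <- rj$residue_name %in% c("ASP", "GLU")
      basic_j <- rj$residue_name %in% c("LYS", "ARG")
      acidic_i <- ri$residue_name %in% c("ASP", "GLU")
      d <- sqrt((ri$x - rj$x)^2 + (ri$y - rj$y)^2 + (ri$z - rj$z)^2)
      if (((basic_i && acidic_j) || (basic_j && acidic_i)) && d <= 4.0)
        n_expected <- n_expected + 1L
    }
    expect_equal(nrow(found), n_expected)
  }
})

test_that("buried area matches the two-sphere closed form and behaves", {
  s1 <- make_model(matrix(0, 1, 3))
  far <- make_model(matrix(c(100, 0, 0), 1))
  expect_lt(abs(buried_area(s1, far)), 1)

  # two equal spheres: per-side buried area = 2 pi re h, h = re - d/2
  re <- 1.70 + 1.4
  for (d in c(2, 3, 4, 5)) {
    s2 <- make_model(matrix(c(d, 0, 0), 1))
    analytic <- 2 * pi * re * (re - d / 2)
    expect_lt(abs(buried_area(s1, s2) - analytic) / analytic, 0.02)
    # symmetry and the total flag
    expect_equal(buried_area(s1, s2), buried_area(s2, s1))
    expect_equal(buried_area(s1, s2, total = TRUE), 2 * buried_area(s1, s2))
  }

  # monotone decrease while pulling the same partner apart
  set.seed(53)
  a <- make_model(random_cloud(15, 4))
  b0 <- random_cloud(15, 4)
  areas <- vapply(c(0, 2, 4, 7, 12), function(sep)
    buried_area(a, make_model(b0 + matrix(c(8 + sep, 0, 0), 15, 3,
                                          byrow = TRUE))), numeric(1))
  expect_true(all(diff(areas) <= 1e-9))

  # rigid-transform invariance within the sphere-sampling resolution
  b <- make_model(random_cloud(15, 4) + matrix(c(6, 0, 0), 15, 3,
                                               byrow = TRUE))
  base <- buried_area(a, b)
  R <- rotation_about_axis(c(1, 1, 0), 35)
  move <- function(m) set_coords(m, sweep(coords(m) %*% t(R), 2,
                                          c(3, -2, 9), "+"))
  expect_equal(buried_area(move(a), move(b)), base, tolerance = 0.02)
})
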