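# Prolate Caspar-Klug lattice: closed-form counts, geometric construction,
# fiber sites and stoichiometry.

test_that("capsomer counts match the closed form for the reference shells", {
  expect_equal(capsomer_counts(3, 5, connector_vertex = TRUE),
               c(n_pentamer = 11, n_hexamer = 30, n_major_subunits = 235))
  expect_equal(capsomer_counts(1, 1),
               c(n_pentamer = 12, n_hexamer = 0, n_major_subunits = 60))
  expect_equal(unname(capsomer_counts(3, 3)["n_hexamer"]), 20)
  expect_equal(unname(capsomer_counts(3, 3)["n_major_subunits"]), 180)
  expect_error(capsomer_counts(2, 2), "triangulation")
  expect_error(capsomer_counts(3, 2), "Q must")
})

test_that("built lattices agree with the closed-form counts", {
  for (tq in list(c(1, 1), c(1, 3), c(3, 3), c(3, 4), c(3, 5), c(3, 7),
                  c(3, 9))) {
    lat <- build_lattice(lattice_spec(tq[1], tq[2], 400))
    cnt <- capsomer_counts(tq[1], tq[2])
    expect_equal(sum(lat$type == "hexamer"), unname(cnt["n_hexamer"]))
    expect_equal(sum(lat$type == "pentamer"), unname(cnt["n_pentamer"]))
  }
  expect_error(build_lattice(lattice_spec(4, 4)), "T in \\{1, 3\\}")
})

test_that("the phi29 lattice has the documented zones, classes and extent", {
  lat <- build_lattice(lattice_spec(3, 5, 400, connector_vertex = TRUE))
  expect_equal(nrow(lat), 42)  # 41 capsomers + 1 connector site
  expect_equal(sum(lat$zone == "equator"), 10)
  expect_setequal(lat$class_label[lat$zone == "equator"], c("H3", "H4"))
  expect_equal(sum(lat$type == "connector"), 1)
  # the connector sits at the bottom apex next to the H6 ring
  con <- lat[lat$type == "connector", ]
  expect_equal(con$z, min(lat$z))
  # length ~ 1.3 x width for this spec, within 5%
  len <- diff(range(lat$z))
  wid <- 2 * max(sqrt(lat$x^2 + lat$y^2))
  expect_lt(abs(len - 1.3 * 400) / (1.3 * 400), 0.05)
  expect_lt(abs(wid - 400) / 400, 0.05)
})

test_that("T=1 Q=1 is a regular icosahedron of pentamers", {
  lat <- build_lattice(lattice_spec(1, 1, 100))
  expect_equal(nrow(lat), 12)
  expect_true(all(lat$type == "pentamer"))
  d <- as.matrix(dist(lat[, c("x", "y", "z")]))
  nn <- apply(d + diag(1e9, 12), 1, min)
  expect_lt(max(nn) - min(nn), 1e-6)
})

test_that("the capsomer adjacency graph is a closed triangulated shell", {
  # V - E + F = 2 with F counted as adjacency triangles, and CK degrees
  for (tq in list(c(1, 1), c(1, 2), c(3, 3), c(3, 4), c(3, 5), c(3, 7))) {
    lat <- build_lattice(lattice_spec(tq[1], tq[2], 400))
    e <- attr(lat, "edges")
    nbr <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    n_tri <- 0
    for (i in seq_len(nrow(e)))
      n_tri <- n_tri + length(intersect(nbr[[as.character(e[i, 1])]],
                                        nbr[[as.character(e[i, 2])]]))
    n_tri <- n_tri / 3
    expect_equal(nrow(lat) - nrow(e) + n_tri, 2)
    deg <- table(factor(c(e[, 1], e[, 2]), levels = lat$site_id))
    expect_true(all(deg[lat$type == "pentamer"] == 5))
    if (any(lat$type == "hexamer"))
      expect_true(all(deg[lat$type == "hexamer"] == 6))
  }
})

test_that("lattice site set is C5- and D5-invariant before connector assignment", {
  lat <- build_lattice(lattice_spec(3, 5, 400))
  xyz <- as.matrix(lat[, c("x", "y", "z")])
  set_dist <- function(a, b) {
    d <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)),
                                      nrow(a) + seq_len(nrow(b))]
    max(apply(d, 1, min))
  }
  R5 <- rotation_about_axis(c(0, 0, 1), 72)
  expect_lt(set_dist(xyz %*% t(R5), xyz), 1e-6)
  # C2 axis in the equatorial plane at azimuth 18 degrees completes D5
  C2 <- rotation_about_axis(c(cos(pi / 10), sin(pi / 10), 0), 180)
  expect_lt(set_dist(xyz %*% t(C2), xyz), 1e-6)
})

test_that("fiber sites sit at pentamer-adjacent quasi-3-fold junctions", {
  with_con <- build_lattice(lattice_spec(3, 5, 400, connector_vertex = TRUE))
  expect_equal(nrow(enumerate_fiber_sites(with_con)), 55)
  no_con <- build_lattice(lattice_spec(3, 5, 400))
  fib <- enumerate_fiber_sites(no_con)
  expect_equal(nrow(fib), 60)
  # each junction references one pentamer and two distinct hexamers, and
  # its three capsomer centres are mutually close (adjacency sanity)
  expect_true(all(fib$hexamer_id1 != fib$hexamer_id2))
  xyz <- as.matrix(no_con[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  med_nn <- median(apply(d + diag(1e9, nrow(d)), 1, min))
  for (i in seq_len(nrow(fib))) {
    tri <- match(c(fib$pentamer_id[i], fib$hexamer_id1[i],
                   fib$hexamer_id2[i]), no_con$site_id)
    expect_lt(max(dist(xyz[tri, ])), 1.5 * med_nn)
  }
})

test_that("stoichiometry reproduces the phi29 copy numbers", {
  st <- stoichiometry(lattice_spec(3, 5, 400, connector_vertex = TRUE))
  get <- function(p) st$copies[st$protein == p]
  expect_equal(get("major_capsid"), 235)
  expect_equal(get("head_fiber"), 165)   # 55 trimeric fibers
  expect_equal(get("connector"), 12)
  expect_equal(get("appendage"), 36)     # 12 trimeric spikes
  expect_equal(st$per_asym_unit[st$protein == "major_capsid"], 47)
  expect_equal(st$per_asym_unit[st$protein == "head_fiber"], 33)
})
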