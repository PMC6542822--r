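# Prolate Caspar-Klug lattice construction for 5-fold elongated capsids.
#
# The shell is modelled as a spherocylinder: two icosahedral end caps
# (hemispheres of radius width/2, 5-fold axis on z) joined by a cylindrical
# equatorial band carrying (Q - T) inserted rings of 5 hexamers.  Capsomer
# positions in the caps come from the regular icosahedron (vertices ->
# pentamers; for T = 3, face centres -> hexamers); adjacency is assigned
# combinatorially from the ring structure so that the capsomer graph is the
# exact Caspar-Klug triangulation (pentamers touch 5 hexamers, hexamers 6
# neighbours, no pentamer-pentamer contacts for T = 3).

.is_ck_number <- function(T) {
  for (h in 0:ceiling(sqrt(T))) for (k in 0:ceiling(sqrt(T)))
    if (h + k > 0 && h * h + h * k + k * k == T) return(TRUE)
  FALSE
}

#' Capsomer counts of a prolate Caspar-Klug shell (closed form)
#'
#' For end-cap triangulation number T and elongation number Q >= T on a
#' 5-fold prolate shell: n_hexamer = 10(T - 1) + 5(Q - T), n_pentamer = 12
#' minus one if a vertex is replaced by the portal/connector, and the major
#' capsid protein count is 6 per hexamer plus 5 per pentamer.  phi29
#' (T = 3, Q = 5, connector vertex) gives 11 pentamers, 30 hexamers and 235
#' major capsid subunits.
#'
#' @param T triangulation number of the end caps (a valid CK number:
#'   1, 3, 4, 7, ...)
#' @param Q elongation number, integer >= T
#' @param connector_vertex replace one 5-fold vertex by the connector?
#' @return named numeric vector: n_pentamer, n_hexamer, n_major_subunits
#' @export
capsomer_counts <- function(T, Q = T, connector_vertex = FALSE) {
  if (T != round(T) || T < 1 || !.is_ck_number(T))
    stop("T = ", T, " is not a valid Caspar-Klug triangulation number")
  if (Q != round(Q) || Q < T) stop("Q must be an integer >= T")
  n_hex <- 10 * (T - 1) + 5 * (Q - T)
  n_pent <- 12 - as.integer(connector_vertex)
  c(n_pentamer = n_pent, n_hexamer = n_hex,
    n_major_subunits = 6 * n_hex + 5 * n_pent)
}

#' Prolate lattice specification
#'
#' @param T end-cap triangulation number (supported geometrically: 1 or 3)
#' @param Q elongation number >= T
#' @param width target outer width (capsomer centre diameter), Angstrom
#' @param connector_vertex replace the bottom apex pentamer by the connector
#' @return list of class `lattice_spec`
#' @export
lattice_spec <- function(T = 3, Q = 5, width = 400, connector_vertex = FALSE) {
  capsomer_counts(T, Q)  # validates T, Q
  if (width <= 0) stop("width must be positive")
  structure(list(T = as.integer(T), Q = as.integer(Q), width = width,
                 connector_vertex = isTRUE(connector_vertex)),
            class = "lattice_spec")
}

# Icosahedron reference angles (5-fold axis on z): polar angles of the
# vertex ring and of the two face-centre rings of the upper half.
.icosa_angles <- function() {
  phi_g <- (1 + sqrt(5)) / 2
  theta_v <- atan2(2, 1)                      # 63.4349 deg, vertex ring
  # face centres: apex faces (apex + 2 ring vertices) and band faces
  apex <- c(0, 0, 1)
  v <- function(az) c(sin(theta_v) * cos(az), sin(theta_v) * sin(az),
                      cos(theta_v))
  f1 <- apex + v(0) + v(2 * pi / 5)
  f2 <- v(0) + v(2 * pi / 5) + c(sin(pi - theta_v) * cos(pi / 5),
                                 sin(pi - theta_v) * sin(pi / 5),
                                 cos(pi - theta_v))
  list(theta_v = theta_v,
       theta_f1 = acos(f1[3] / sqrt(sum(f1^2))),
       theta_f2 = acos(f2[3] / sqrt(sum(f2^2))))
}

#' Build a prolate Caspar-Klug capsomer lattice
#'
#' Places capsomer centres on a spherocylinder (hemispherical end caps of
#' radius width/2 joined by a cylinder) with the 5-fold axis on z, and
#' records the exact capsomer adjacency graph of the lattice.  Supported end
#' caps: T = 1 (pentamers only) and T = 3 (the phi29 cap); any Q >= T.
#' Hexamer class labels H1, H2, ... are assigned per C5 ring orbit in order
#' of decreasing z; for T = 3, Q = 5 this reproduces the conventional
#' labelling with H3/H4 equatorial and H6 adjacent to the connector vertex.
#'
#' @param spec lattice_spec (or arguments forwarded to [lattice_spec])
#' @return data.frame of class `capsid_lattice`: one row per capsomer site
#'   with columns site_id, x, y, z, type (pentamer/hexamer/connector), zone
#'   (cap_top/equator/cap_bottom), class_label, ring.  The exact adjacency
#'   edge list is in `attr(, "edges")` (2-column matrix of site_ids) and the
#'   spec in `attr(, "spec")`.
#' @export
build_lattice <- function(spec = lattice_spec()) {
  if (!inherits(spec, "lattice_spec")) stop("spec must be a lattice_spec")
  if (!(spec$T %in% c(1L, 3L)))
    stop("geometric construction implemented for T in {1, 3} only ",
         "(T = ", spec$T, " requested)")
  T <- spec$T; Q <- spec$Q
  R <- spec$width / 2
  m <- Q - T                                   # inserted equatorial rings
  L <- 0.3 * R * m                             # cylinder length
  ang <- .icosa_angles()

  # ring stack, top to bottom; each ring: n sites, type, geometry
  rings <- list()
  add <- function(n, type, theta = NA, z = NA, rho = NA, zone) {
    rings[[length(rings) + 1]] <<- list(n = n, type = type, theta = theta,
                                        z = z, rho = rho, zone = zone)
  }
  add(1, "pentamer", theta = 0, zone = "cap_top")
  if (T == 3) {
    add(5, "hexamer", theta = ang$theta_f1, zone = "cap_top")
    add(5, "pentamer", theta = ang$theta_v, zone = "cap_top")
    add(5, "hexamer", theta = ang$theta_f2, zone = "cap_top")
  } else {
    add(5, "pentamer", theta = ang$theta_v, zone = "cap_top")
  }
  if (m > 0) for (i in seq_len(m))
    add(5, "hexamer", z = L / 2 - (i - 0.5) * L / m, rho = R, zone = "equator")
  if (T == 3) {
    add(5, "hexamer", theta = pi - ang$theta_f2, zone = "cap_bottom")
    add(5, "pentamer", theta = pi - ang$theta_v, zone = "cap_bottom")
    add(5, "hexamer", theta = pi - ang$theta_f1, zone = "cap_bottom")
  } else {
    add(5, "pentamer", theta = pi - ang$theta_v, zone = "cap_bottom")
  }
  add(1, "pentamer", theta = pi, zone = "cap_bottom")

  # azimuthal offsets: apexes have none; 5-rings alternate 36 / 0 degrees
  # down the stack (this alternation is what makes consecutive rings
  # antiprismatic and the whole site set D5-symmetric)
  five_idx <- which(vapply(rings, function(r) r$n == 5, TRUE))
  for (j in seq_along(five_idx))
    rings[[five_idx[j]]]$offset <- if (j %% 2 == 1) 36 else 0

  # site coordinates
  site_rows <- list()
  sid <- 0L
  for (ri in seq_along(rings)) {
    r <- rings[[ri]]
    if (!is.na(r$theta)) {
      cap_sign <- if (r$theta <= pi / 2 + 1e-12) 1 else -1
      z <- cap_sign * L / 2 + R * cos(r$theta)
      rho <- R * sin(r$theta)
    } else {
      z <- r$z; rho <- r$rho
    }
    az <- if (r$n == 1) 0 else (r$offset + 72 * (seq_len(r$n) - 1))
    for (k in seq_len(r$n)) {
      sid <- sid + 1L
      site_rows[[sid]] <- data.frame(
        site_id = sid, ring = ri, pos = k,
        x = rho * cos(az[k] * pi / 180), y = rho * sin(az[k] * pi / 180),
        z = z, az = wrap360(az[k]),
        type = r$type, zone = r$zone, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)

  # adjacency: combinatorial rules of the CK triangulation
  edges <- list()
  push <- function(a, b) edges[[length(edges) + 1]] <<- cbind(a, b)
  ring_sites <- split(sites$site_id, sites$ring)
  ring_az <- split(sites$az, sites$ring)
  nr <- length(rings)
  is_apex <- vapply(rings, function(r) r$n == 1, TRUE)
  nearest_in <- function(from_ring, to_ring, n_nearest) {
    ids_a <- ring_sites[[from_ring]]; az_a <- ring_az[[from_ring]]
    ids_b <- ring_sites[[to_ring]];   az_b <- ring_az[[to_ring]]
    for (i in seq_along(ids_a)) {
      d <- ang_diff(az_a[i], az_b)
      nb <- ids_b[order(d)[seq_len(n_nearest)]]
      for (b in nb) push(ids_a[i], b)
    }
  }
  for (ri in seq_len(nr)) {
    r <- rings[[ri]]
    if (is_apex[ri]) {
      adj <- if (ri == 1) 2 else nr - 1
      for (b in ring_sites[[adj]]) push(ring_sites[[ri]], b)
      next
    }
    # in-ring contacts: every ring for T = 1; for T = 3 only the hexamer
    # rings surrounding an apex (the ring circumference elsewhere exceeds
    # the capsomer spacing)
    if (T == 1 || is_apex[ri - 1] || is_apex[ri + 1]) {
      ids <- ring_sites[[ri]]
      for (k in seq_along(ids)) push(ids[k], ids[k %% length(ids) + 1])
    }
    # antiprism contacts with the next 5-ring down
    if (ri + 1 <= nr && !is_apex[ri + 1]) nearest_in(ri, ri + 1, 2)
    # same-azimuth contacts two rings down (T = 3 band geometry)
    if (T == 3 && ri + 2 <= nr && !is_apex[ri + 2]) nearest_in(ri, ri + 2, 1)
  }
  edges <- unique(t(apply(do.call(rbind, edges), 1, sort)))

  # connector assignment: bottom apex (tail vertex, z minimum)
  if (spec$connector_vertex) {
    bot <- sites$site_id[which.min(sites$z)]
    sites$type[sites$site_id == bot] <- "connector"
  }

  # class labels: hexamer rings H1, H2, ... in order of decreasing mean z;
  # pentamers labelled P, the connector CON
  hex_rings <- sort(unique(sites$ring[sites$type == "hexamer"]))
  hex_z <- vapply(hex_rings, function(ri) mean(sites$z[sites$ring == ri]),
                  numeric(1))
  hex_rank <- hex_rings[order(-hex_z)]
  sites$class_label <- "P"
  for (j in seq_along(hex_rank))
    sites$class_label[sites$ring == hex_rank[j] & sites$type == "hexamer"] <-
      paste0("H", j)
  sites$class_label[sites$type == "connector"] <- "CON"

  out <- sites[, c("site_id", "x", "y", "z", "type", "zone", "class_label",
                   "ring")]
  counts <- capsomer_counts(T, Q, spec$connector_vertex)
  stopifnot(sum(out$type == "hexamer") == counts["n_hexamer"],
            sum(out$type == "pentamer") == counts["n_pentamer"])
  attr(out, "edges") <- unname(edges)
  attr(out, "spec") <- spec
  class(out) <- c("capsid_lattice", "data.frame")
  out
}

#' @export
print.capsid_lattice <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("capsid_lattice T=%d Q=%d width=%g A%s\n", s$T, s$Q, s$width,
              if (s$connector_vertex) " (connector vertex)" else ""))
  print(table(type = x$type, zone = x$zone))
  invisible(x)
}

#' Enumerate head-fiber sites (pentamer-adjacent quasi-3-fold junctions)
#'
#' Head fibers sit at the local 3-fold junctions where one pentameric and two
#' hexameric capsomeres meet; junctions between three hexamers carry no
#' fiber, and the connector vertex carries none.  Each junction is one
#' triangle of the capsomer adjacency graph with exactly one pentamer.  For
#' the phi29 lattice (T = 3, Q = 5, connector vertex) this yields the 55
#' head-fiber positions (5 per pentamer).
#'
#' @param sites capsid_lattice from [build_lattice]
#' @return data.frame: one row per fiber site with the junction centroid
#'   (x, y, z) and the pentamer/hexamer site ids
#' @export
enumerate_fiber_sites <- function(sites) {
  stopifnot(inherits(sites, "capsid_lattice"))
  edges <- attr(sites, "edges")
  nbr <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  out <- list()
  for (p in sites$site_id[sites$type == "pentamer"]) {
    hx <- intersect(nbr[[as.character(p)]],
                    sites$site_id[sites$type == "hexamer"])
    if (length(hx) < 2) next
    for (i in seq_len(length(hx) - 1)) for (j in (i + 1):length(hx)) {
      a <- hx[i]; b <- hx[j]
      if (b %in% nbr[[as.character(a)]]) {
        tri <- c(p, a, b)
        ctr <- colMeans(sites[match(tri, sites$site_id), c("x", "y", "z")])
        out[[length(out) + 1]] <- data.frame(
          x = ctr[1], y = ctr[2], z = ctr[3],
          pentamer_id = p, hexamer_id1 = min(a, b), hexamer_id2 = max(a, b))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               pentamer_id = integer(0), hexamer_id1 = integer(0),
               hexamer_id2 = integer(0))
  rownames(res) <- NULL
  res
}

#' Protein stoichiometry of the assembled head
#'
#' Copy numbers implied by the lattice: the major capsid protein contributes
#' 6 copies per hexamer and 5 per pentamer; each head fiber is a homotrimer
#' of the fiber protein (3 copies per fiber site); the portal/connector is a
#' dodecamer occupying one vertex.  When the connector vertex is present the
#' tail stoichiometry it nucleates is included: a dodecameric lower collar,
#' 12 trimeric appendages (36 copies) and a knob of 6 copies.  Per
#' asymmetric-unit values are totals / 5 (the head is C5) where divisible.
#'
#' @param spec lattice_spec
#' @return data.frame with columns protein, copies, per_asym_unit
#' @export
stoichiometry <- function(spec = lattice_spec()) {
  stopifnot(inherits(spec, "lattice_spec"))
  lat <- build_lattice(spec)
  fib <- enumerate_fiber_sites(lat)
  counts <- capsomer_counts(spec$T, spec$Q, spec$connector_vertex)
  rows <- data.frame(
    protein = c("major_capsid", "head_fiber"),
    copies = c(unname(counts["n_major_subunits"]), 3 * nrow(fib)),
    stringsAsFactors = FALSE)
  if (spec$connector_vertex)
    rows <- rbind(rows, data.frame(
      protein = c("connector", "lower_collar", "appendage", "tail_knob"),
      copies = c(12, 12, 36, 6)))
  rows$per_asym_unit <- ifelse(rows$copies %% 5 == 0, rows$copies / 5, NA)
  rows
}

#' Pseudo-atom model of a lattice
#'
#' One CA pseudo-atom (carbon) per capsomer or fiber site, residue number =
#' site index; useful for exporting a lattice to PDB for inspection.
#'
#' @param sites capsid_lattice
#' @param fibers optional data.frame from [enumerate_fiber_sites]; fiber
#'   pseudo-atoms are written as chain F
#' @return structure_model
#' @export
lattice_model <- function(sites, fibers = NULL) {
  m <- make_model(as.matrix(sites[, c("x", "y", "z")]), chain = "L",
                  resno = sites$site_id, label = "capsid_lattice")
  if (!is.null(fibers) && nrow(fibers))
    m <- combine_models(m, make_model(as.matrix(fibers[, c("x", "y", "z")]),
                                      chain = "F", label = "fibers"),
                        label = "capsid_lattice")
  m
}
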