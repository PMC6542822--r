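# Synthetic-structure generators with planted ground truth.  Every
# generator is deterministic given (seed, parameters); each derives its own
# RNG stream from the user seed and a per-generator key, so adding
# parameters to one generator never perturbs the draws of another.

# key derivation: stream seed = (seed * 48271 + hash(key)) mod (2^31 - 1)
.derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               h) %% 2147483647L
}

.with_stream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.derive_seed(seed, key))
  force(expr)
}

# merge angular intervals (degrees, mod 360) given as 2-col matrix
.merge_intervals_mod360 <- function(iv) {
  if (!nrow(iv)) return(iv)
  pieces <- list()
  for (i in seq_len(nrow(iv))) {
    a <- iv[i, 1] %% 360; w <- iv[i, 2] - iv[i, 1]
    if (w >= 360) return(matrix(c(0, 360), 1))
    b <- a + w
    if (b <= 360) pieces[[length(pieces) + 1]] <- c(a, b)
    else {
      pieces[[length(pieces) + 1]] <- c(a, 360)
      pieces[[length(pieces) + 1]] <- c(0, b - 360)
    }
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2] + 1e-12)
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  # wrap-merge first and last
  if (nrow(out) > 1 && out[1, 1] <= 1e-12 && out[nrow(out), 2] >= 360 - 1e-12) {
    out[1, 1] <- out[nrow(out), 1] - 360
    out <- out[-nrow(out), , drop = FALSE]
  }
  out
}

#' Synthetic connector-in-capsid geometry for the rotational clash scan
#'
#' Builds a Cn "connector": a ring body with radial spokes whose tip atoms
#' reach the interface radius, inside a Cm wall of alternating radial
#' (interface-radius, clash-capable) and tangential (recessed, never
#' clashing) blocks.  The radial blocks are sized so that the exact
#' clash-free rotational windows have the requested width; windows repeat
#' with period 360 / lcm(n_mobile, n_wall).  The exact windows are computed
#' by interval arithmetic over all atom pairs (carbon vdW radii, 0.4 A
#' overlap threshold) and returned as ground truth.
#'
#' Spoke tips are CA atoms with residue number 122 and the radial wall
#' blocks are CA atoms with residue number 156, so the named-atom
#' minimum-distance selection of a connector/capsid scan can be exercised
#' verbatim.
#'
#' @param seed integer seed (the construction is deterministic; kept for API
#'   uniformity)
#' @param n_mobile fold of the mobile ring (default 12)
#' @param n_wall fold of the wall (default 5)
#' @param radius interface radius, Angstrom (default 400; large so that one
#'   scan step subtends more than a vdW contact)
#' @param gap_width width of each clash-free window, degrees (default 5)
#' @param overlap_threshold clash threshold, Angstrom (default 0.4)
#' @return list: mobile, fixed (structure_model), truth (list with windows
#'   data.frame, period, gap_width)
#' @export
make_ring_in_wall <- function(seed = 1, n_mobile = 12, n_wall = 5,
                              radius = 400, gap_width = 5,
                              overlap_threshold = 0.4) {
  stopifnot(n_mobile >= 1, n_wall >= 1, radius > 0, gap_width >= 0)
  period <- 360 / .lcm(n_mobile, n_wall)
  reach <- 2 * 1.70 - overlap_threshold             # carbon-carbon clash dist
  delta <- 2 * asin(reach / (2 * radius)) * 180 / pi  # its angular subtense
  block_half <- (period - gap_width) / 2 - delta
  if (block_half <= 0)
    stop("geometrically impossible: gap width ", gap_width,
         " leaves no room for wall blocks at period ", period,
         " degrees (need gap < ", round(period - 2 * delta, 2), ")")
  deg <- pi / 180
  ring_xyz <- function(r, az_deg, z = 0)
    cbind(r * cos(az_deg * deg), r * sin(az_deg * deg), z)

  # mobile: Cn ring body (recessed) + one radial spoke per fold
  spoke_r <- seq(radius - 28, radius, by = 4)
  mob_rows <- list()
  for (k in seq_len(n_mobile) - 1) {
    az <- k * 360 / n_mobile
    body <- ring_xyz(radius - 40, az + c(-6, 0, 6))
    spoke <- ring_xyz(spoke_r, az)
    mob_rows[[k + 1]] <- data.frame(
      atom_name = "CA", residue_name = "TYR", residue_number = 200L,
      chain_id = "M", element = "C",
      x = c(body[, 1], spoke[, 1]), y = c(body[, 2], spoke[, 2]),
      z = c(body[, 3], spoke[, 3]), stringsAsFactors = FALSE)
  }
  mob_at <- do.call(rbind, mob_rows)
  # spoke tip atoms (at the interface radius) carry residue number 122
  is_tip <- abs(sqrt(mob_at$x^2 + mob_at$y^2) - radius) < 1e-6
  mob_at$residue_number <- ifelse(is_tip, 122L, 200L)
  mobile <- structure_model(mob_at, label = "synthetic_connector_ring")

  # wall: radial blocks (clash-capable, resno 156) + tangential blocks
  blk_step <- min(delta / 2, block_half)
  blk_az <- unique(c(seq(-block_half, block_half, by = blk_step), block_half))
  wall_rows <- list()
  for (j in seq_len(n_wall) - 1) {
    az0 <- j * 360 / n_wall
    rad_blk <- ring_xyz(radius, az0 + blk_az)
    tan_blk <- ring_xyz(radius + 20, az0 + 180 / n_wall + seq(-10, 10, by = 2))
    wall_rows[[j + 1]] <- data.frame(
      atom_name = "CA", residue_name = c(rep("TRP", nrow(rad_blk)),
                                         rep("GLY", nrow(tan_blk))),
      residue_number = c(rep(156L, nrow(rad_blk)),
                         rep(300L, nrow(tan_blk))),
      chain_id = "W", element = "C",
      x = c(rad_blk[, 1], tan_blk[, 1]), y = c(rad_blk[, 2], tan_blk[, 2]),
      z = 0, stringsAsFactors = FALSE)
  }
  fixed <- structure_model(do.call(rbind, wall_rows),
                           label = "synthetic_capsid_wall")

  # exact clash-free windows: for every (mobile, wall) atom pair the set of
  # scan angles theta placing them within clash distance is an interval;
  # the truth is the complement of the union
  xm <- coords(mobile); xf <- coords(fixed)
  rm_ <- sqrt(xm[, 1]^2 + xm[, 2]^2); am <- atan2(xm[, 2], xm[, 1]) / deg
  rf <- sqrt(xf[, 1]^2 + xf[, 2]^2); af <- atan2(xf[, 2], xf[, 1]) / deg
  blocked <- list()
  for (i in seq_len(nrow(xm))) {
    dz2 <- (xm[i, 3] - xf[, 3])^2
    cos_max <- (rm_[i]^2 + rf^2 + dz2 - reach^2) / (2 * rm_[i] * rf)
    can <- cos_max < 1
    if (!any(can)) next
    if (any(cos_max <= -1))
      stop("geometrically impossible: an atom pair clashes at every angle")
    dmax <- acos(pmax(cos_max[can], -1)) / deg
    ctr <- af[can] - am[i]
    blocked[[length(blocked) + 1]] <- cbind(ctr - dmax, ctr + dmax)
  }
  blk <- .merge_intervals_mod360(do.call(rbind, blocked))
  # complement on [0, 360)
  windows <- list()
  if (!nrow(blk)) windows[[1]] <- c(0, 360)
  else {
    for (i in seq_len(nrow(blk))) {
      nxt <- if (i < nrow(blk)) blk[i + 1, 1] else blk[1, 1] + 360
      if (nxt - blk[i, 2] > 1e-9)
        windows[[length(windows) + 1]] <- c(blk[i, 2], nxt)
    }
  }
  w <- do.call(rbind, windows)
  truth <- data.frame(start = wrap360(w[, 1]), end = w[, 2],
                      width = w[, 2] - w[, 1])
  truth$end <- truth$start + truth$width
  list(mobile = mobile, fixed = fixed,
       truth = list(windows = truth[order(truth$start), ],
                    period = period, gap_width = gap_width))
}

.lcm <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a * b / g(a, b)
}

#' Synthetic two-state assembly with planted shift and hinge
#'
#' A Cn ring assembly ("connector") plus a larger C5 ring ("capsid" frame),
#' in two states: state b is the connector shifted axially by `shift`
#' Angstrom, with each subunit optionally hinge-rotated by `hinge` degrees
#' about a tangential axis through its own centroid (a level motion that
#' changes conformation without moving the centre of gravity).  Both
#' state-b models are then jointly moved by a random rigid nuisance
#' transform, so recovering the shift requires superposing the frames.
#'
#' @param seed integer seed
#' @param shift planted axial displacement, Angstrom (default 13, the
#'   connector's outward shift upon head maturation)
#' @param hinge planted per-subunit hinge angle, degrees (default 0)
#' @param n_fold connector fold (default 12)
#' @return list: state_a, state_b, frame_a, frame_b (structure_model),
#'   truth (shift_vector, shift, hinge)
#' @export
make_two_state <- function(seed = 1, shift = 13, hinge = 0, n_fold = 12) {
  .with_stream(seed, "two_state", {
    # one connector subunit: a rigid 18-atom wedge at radius ~70
    local_xyz <- cbind(runif(18, -6, 6), runif(18, -4, 4), runif(18, -15, 15))
    monomer <- make_model(sweep(local_xyz, 2, c(70, 0, 0), "+"),
                          chain = "A", resno = 1:18, label = "gp10_like")
    state_a <- expand_assembly(monomer, cyclic_group(n_fold))
    # frame: C5 ring of larger blobs at radius 190 (capsid-like)
    frame_xyz <- cbind(runif(40, -12, 12), runif(40, -12, 12),
                       runif(40, -30, 30))
    frame_mono <- make_model(sweep(frame_xyz, 2, c(190, 0, 0), "+"),
                             chain = "F", resno = 1:40, label = "capsid_like")
    frame_a <- expand_assembly(frame_mono, cyclic_group(5))

    xyz_b <- coords(state_a)
    if (hinge != 0) {
      chains <- state_a$atoms$chain_id
      for (ch in unique(chains)) {
        idx <- which(chains == ch)
        ctr <- colMeans(xyz_b[idx, , drop = FALSE])
        tangent <- c(-ctr[2], ctr[1], 0)
        tangent <- tangent / sqrt(sum(tangent^2))
        R <- rotation_about_axis(tangent, hinge)
        xyz_b[idx, ] <- sweep(sweep(xyz_b[idx, , drop = FALSE], 2, ctr) %*%
                                t(R), 2, ctr, "+")
      }
    }
    xyz_b <- sweep(xyz_b, 2, c(0, 0, shift), "+")
    state_b <- set_coords(state_a, xyz_b)
    frame_b <- frame_a
    # nuisance rigid transform applied jointly to state_b and frame_b
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    Rn <- rotation_about_axis(ax, runif(1, 0, 360))
    tn <- runif(3, -25, 25)
    nudge <- function(m) set_coords(m, sweep(coords(m) %*% t(Rn), 2, tn, "+"))
    list(state_a = state_a, state_b = nudge(state_b),
         frame_a = frame_a, frame_b = nudge(frame_b),
         truth = list(shift_vector = c(0, 0, shift), shift = shift,
                      hinge = hinge))
  })
}

#' Synthetic head/tail orientation set
#'
#' Head orientations are drawn quasi-uniformly (alt restricted to
#' [10, 170] degrees to stay clear of the gimbal poles); tail azimuths
#' follow the head azimuth plus an offset that is near-constant ("fixed",
#' Gaussian jitter sigma `jitter_sd`), uniform on [0, 360) ("free"), or
#' wrapped-normal with the stated half-width ("oscillating"; half-width =
#' 2 sigma).  alt and phi of the tail track the head within ~2 degrees.  A
#' planted fraction of outliers receives an alt deviation of 10 degrees
#' (greater than the 5-degree screening threshold) so that pair filtering
#' can be validated by construction.
#'
#' @param seed integer seed
#' @param n_particles number of particles (default 1000)
#' @param mode "fixed", "free" or "oscillating"
#' @param offset base azimuth offset, degrees (default 0)
#' @param jitter_sd sigma of the fixed-mode azimuth jitter, degrees
#'   (default 1)
#' @param half_width oscillation half-width, degrees (default 3;
#'   oscillating mode only)
#' @param outlier_fraction fraction of particles with planted alt outliers
#' @return list: head, tail (orientation data.frames), pairs (merged pair
#'   table), truth (mode, offset, outlier_ids, half_width)
#' @export
make_orientation_set <- function(seed = 1, n_particles = 1000,
                                 mode = c("fixed", "free", "oscillating"),
                                 offset = 0, jitter_sd = 1, half_width = 3,
                                 outlier_fraction = 0) {
  mode <- match.arg(mode)
  stopifnot(n_particles >= 1, outlier_fraction >= 0, outlier_fraction <= 1)
  .with_stream(seed, "orientation_set", {
    n <- n_particles
    alt <- acos(runif(n, cos(170 * pi / 180), cos(10 * pi / 180))) * 180 / pi
    az <- runif(n, 0, 360)
    phi <- runif(n, 0, 360)
    d_az <- switch(mode,
                   fixed = rnorm(n, 0, jitter_sd),
                   free = runif(n, 0, 360),
                   oscillating = rnorm(n, 0, half_width / 2))
    alt_t <- alt + pmax(pmin(rnorm(n, 0, 0.5), 2), -2)
    phi_t <- phi + pmax(pmin(rnorm(n, 0, 0.5), 2), -2)
    n_out <- round(outlier_fraction * n)
    outlier_ids <- if (n_out > 0) sample.int(n, n_out) else integer(0)
    if (n_out > 0)
      alt_t[outlier_ids] <- alt_t[outlier_ids] +
        ifelse(alt[outlier_ids] > 90, -10, 10)
    ids <- sprintf("p%05d", seq_len(n))
    head <- data.frame(particle_id = ids, alt = alt, az = wrap360(az),
                       phi = wrap360(phi), stringsAsFactors = FALSE)
    tail <- data.frame(particle_id = ids, alt = pmin(pmax(alt_t, 0), 180),
                       az = wrap360(az + offset + d_az),
                       phi = wrap360(phi_t), stringsAsFactors = FALSE)
    list(head = head, tail = tail, pairs = orientation_pairs(head, tail),
         truth = list(mode = mode, offset = offset,
                      outlier_ids = ids[sort(outlier_ids)],
                      half_width = if (mode == "oscillating") half_width
                      else NA_real_))
  })
}

#' Synthetic funnel (lower-collar-like) two-state pair
#'
#' A pseudo-atom funnel with a wide mouth and a two-layer tube stem of the
#' stated outer and inner diameters, plus a copy with a planted radial
#' expansion of the narrow (distal) end and a planted radial contraction of
#' the remaining stem.  Residue numbers increase down the axis, one residue
#' per ring, so region selections can be made by residue range; the truth
#' lists the ranges.
#'
#' @param seed integer seed (construction is deterministic)
#' @param stem_length,mouth_length Angstrom (defaults 180 and 40)
#' @param stem_outer_diameter,stem_inner_diameter Angstrom (defaults 55 and
#'   32, vdW surface-to-surface)
#' @param mouth_outer_diameter Angstrom (default 144)
#' @param expand_narrow planted radial expansion of the narrow end,
#'   Angstrom (default 8, i.e. +16 in diameter)
#' @param contract_stem planted radial contraction of the stem, Angstrom
#'   (default 1.4)
#' @return list: state_a, state_b, truth (ranges and planted amplitudes)
#' @export
make_funnel <- function(seed = 1, stem_length = 180, mouth_length = 40,
                        stem_outer_diameter = 55, stem_inner_diameter = 32,
                        mouth_outer_diameter = 144, expand_narrow = 8,
                        contract_stem = 1.4) {
  ring_spacing <- 4; n_per_ring <- 24
  vdw_c <- 1.70
  r_out <- stem_outer_diameter / 2 - vdw_c
  r_in <- stem_inner_diameter / 2 + vdw_c
  if (r_in >= r_out) stop("inner diameter too close to outer diameter")
  r_mouth <- mouth_outer_diameter / 2 - vdw_c
  az <- seq(0, 360 - 360 / n_per_ring, by = 360 / n_per_ring) * pi / 180
  rows <- list(); resno <- 0L
  add_ring <- function(r, z) {
    resno <<- resno + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      atom_name = sprintf("C%02d", seq_len(n_per_ring)),
      residue_name = "GLY", residue_number = resno,
      chain_id = "A", element = "C",
      x = r * cos(az), y = r * sin(az), z = z, stringsAsFactors = FALSE)
  }
  mouth_z <- seq(0, mouth_length - ring_spacing, by = ring_spacing)
  for (z in mouth_z)
    add_ring(r_mouth + (r_out - r_mouth) * z / mouth_length, z)
  mouth_range <- c(1L, resno)
  stem_z <- seq(mouth_length, mouth_length + stem_length, by = ring_spacing)
  stem_first <- resno + 1L
  narrow_first <- NA_integer_
  narrow_z <- mouth_length + 0.75 * stem_length  # distal quarter of the stem
  for (z in stem_z) {
    if (is.na(narrow_first) && z >= narrow_z) narrow_first <- resno + 1L
    add_ring(r_out, z); add_ring(r_in, z)
  }
  stem_range <- c(stem_first, resno)
  narrow_range <- c(narrow_first, resno)
  at <- do.call(rbind, rows)
  state_a <- structure_model(at, label = "synthetic_funnel_a")
  upper_stem_range <- c(stem_range[1], narrow_range[1] - 1L)
  b <- at
  radial <- sqrt(b$x^2 + b$y^2)
  s <- rep(1, nrow(b))
  in_narrow <- b$residue_number >= narrow_range[1]
  in_upper <- b$residue_number >= upper_stem_range[1] & !in_narrow
  s[in_narrow] <- (radial[in_narrow] + expand_narrow) / radial[in_narrow]
  s[in_upper] <- (radial[in_upper] - contract_stem) / radial[in_upper]
  b$x <- b$x * s; b$y <- b$y * s
  state_b <- structure_model(b, label = "synthetic_funnel_b")
  list(state_a = state_a, state_b = state_b,
       truth = list(mouth_range = mouth_range, stem_range = stem_range,
                    upper_stem_range = upper_stem_range,
                    narrow_range = narrow_range,
                    expand_narrow = expand_narrow,
                    contract_stem = contract_stem,
                    stem_outer_diameter = stem_outer_diameter,
                    stem_inner_diameter = stem_inner_diameter))
}

#' Synthetic mislabelled noisy density map
#'
#' Rasterizes a model at the true pixel size, adds seeded Gaussian noise
#' scaled to the signal RMS, and labels the resulting grid with a different
#' nominal pixel size (the origin is rescaled consistently, i.e. held fixed
#' in voxel units) — the input for magnification calibration.
#'
#' @param seed integer seed
#' @param model reference structure; default: a seeded 40-atom compact blob
#'   (generated from the same seed)
#' @param true_pixel actual Angstrom/pixel of the rasterization (default
#'   1.30)
#' @param nominal_pixel pixel value written in the header (default 1.32)
#' @param dims grid dimensions (default 48^3)
#' @param noise_sd Gaussian noise sigma as a fraction of signal RMS
#'   (default 0.5)
#' @return list: grid (density_grid labelled with the nominal pixel), model,
#'   truth (true_pixel, nominal_pixel, noise_sd)
#' @export
make_noisy_map <- function(seed = 1, model = NULL, true_pixel = 1.30,
                           nominal_pixel = 1.32, dims = c(48, 48, 48),
                           noise_sd = 0.5) {
  stopifnot(true_pixel > 0, nominal_pixel > 0)
  .with_stream(seed, "noisy_map", {
    if (is.null(model)) {
      xyz <- matrix(rnorm(120, 0, 7), ncol = 3)
      xyz <- xyz[sqrt(rowSums(xyz^2)) < 14, , drop = FALSE]
      model <- make_model(xyz, label = "synthetic_calib_reference")
    }
    g <- rasterize(model, voxel = true_pixel, dims = dims)
    rms <- sqrt(mean(g$values^2))
    noisy <- g$values + rnorm(length(g$values), 0, noise_sd * rms)
    grid <- density_grid(noisy, voxel = nominal_pixel,
                         origin = g$origin * (nominal_pixel / true_pixel))
    list(grid = grid, model = model,
         truth = list(true_pixel = true_pixel, nominal_pixel = nominal_pixel,
                      noise_sd = noise_sd))
  })
}
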