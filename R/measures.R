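# Assembly geometry: radial diameter/channel profiles along a symmetry
# axis, salt-bridge detection, and buried (contact) surface area.

#' Radial profile of an assembly along a symmetry axis
#'
#' Slices the model into slabs along `axis` and reports, per slab, the outer
#' radius (maximum over heavy atoms of radial distance + vdW radius) and the
#' inner radius of the axial channel (minimum of radial distance - vdW
#' radius, floored at 0).  Diameters are twice the radii; this
#' surface-to-surface convention across the axis is the one used for all
#' diameter figures in this package.  Slabs containing no atoms are reported
#' as NA (missing), not zero.
#'
#' @param model structure_model
#' @param axis axis direction (default z)
#' @param slab_thickness Angstrom (default 5)
#' @param radii optional vdW radius table (see [vdw_radii])
#' @return data.frame of class `radial_profile`: z_lo, z_hi (axial
#'   coordinates of the slab), n_atoms, outer_radius, inner_radius,
#'   outer_diameter, inner_diameter
#' @export
radial_profile <- function(model, axis = c(0, 0, 1), slab_thickness = 5,
                           radii = NULL) {
  stopifnot(inherits(model, "structure_model"), slab_thickness > 0)
  model <- .heavy(model)
  if (n_atoms(model) == 0) stop("model has no heavy atoms")
  axis <- axis / sqrt(sum(axis^2))
  xyz <- coords(model)
  r_vdw <- vdw_radii(model, radii)
  t_ax <- as.numeric(xyz %*% axis)           # axial coordinate
  radial <- sqrt(pmax(rowSums(xyz^2) - t_ax^2, 0))
  breaks <- seq(floor(min(t_ax) / slab_thickness) * slab_thickness,
                max(t_ax) + slab_thickness, by = slab_thickness)
  bin <- cut(t_ax, breaks, right = FALSE, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(length(breaks) - 1), function(i) {
    in_i <- bin == i
    if (!any(in_i))
      return(data.frame(z_lo = breaks[i], z_hi = breaks[i + 1], n_atoms = 0L,
                        outer_radius = NA_real_, inner_radius = NA_real_))
    data.frame(z_lo = breaks[i], z_hi = breaks[i + 1], n_atoms = sum(in_i),
               outer_radius = max(radial[in_i] + r_vdw[in_i]),
               inner_radius = max(0, min(radial[in_i] - r_vdw[in_i])))
  }))
  out <- out[out$n_atoms > 0 | (seq_len(nrow(out)) > min(which(out$n_atoms > 0)) &
                                  seq_len(nrow(out)) < max(which(out$n_atoms > 0))), ]
  out$outer_diameter <- 2 * out$outer_radius
  out$inner_diameter <- 2 * out$inner_radius
  rownames(out) <- NULL
  class(out) <- c("radial_profile", "data.frame")
  out
}

.basic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.charged_sel <- function(model, table) {
  at <- model$atoms
  keep <- rep(FALSE, nrow(at))
  for (res in names(table))
    keep <- keep | (at$residue_name == res & at$atom_name %in% table[[res]])
  at[keep, , drop = FALSE]
}

#' Detect inter-model salt bridges
#'
#' A salt bridge is counted when a basic side-chain nitrogen (Lys NZ; Arg
#' NE/NH1/NH2; optionally His ND1/NE2) of one model lies within `cutoff` of
#' an acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2) of the other.
#' One entry is reported per residue pair regardless of how many atom pairs
#' qualify.
#'
#' @param a,b structure_model with side-chain atoms
#' @param cutoff Angstrom (default 4.0)
#' @param include_his count histidine as basic (default FALSE)
#' @return data.frame: chain_a, resno_a, resname_a, chain_b, resno_b,
#'   resname_b, min_dist
#' @export
salt_bridges <- function(a, b, cutoff = 4.0, include_his = FALSE) {
  basic_tab <- .basic_atoms
  if (!include_his) basic_tab$HIS <- NULL
  one_dir <- function(m1, m2, swap) {
    bas <- .charged_sel(m1, basic_tab)
    aci <- .charged_sel(m2, .acidic_atoms)
    if (!nrow(bas) || !nrow(aci)) return(NULL)
    d2 <- outer(rowSums(bas[, c("x", "y", "z")]^2),
                rowSums(aci[, c("x", "y", "z")]^2), "+") -
      2 * as.matrix(bas[, c("x", "y", "z")]) %*%
      t(as.matrix(aci[, c("x", "y", "z")]))
    hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    df <- data.frame(
      chain_1 = bas$chain_id[hit[, 1]], resno_1 = bas$residue_number[hit[, 1]],
      resname_1 = bas$residue_name[hit[, 1]],
      chain_2 = aci$chain_id[hit[, 2]], resno_2 = aci$residue_number[hit[, 2]],
      resname_2 = aci$residue_name[hit[, 2]],
      min_dist = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
    if (swap) df[, c(4:6, 1:3, 7)] else df
  }
  cols <- c("chain_a", "resno_a", "resname_a", "chain_b", "resno_b",
            "resname_b", "min_dist")
  fwd <- one_dir(a, b, FALSE)
  if (!is.null(fwd)) names(fwd) <- cols
  rev <- one_dir(b, a, TRUE)
  if (!is.null(rev)) {
    names(rev) <- c("chain_b", "resno_b", "resname_b",
                    "chain_a", "resno_a", "resname_a", "min_dist")
    rev <- rev[, cols]
  }
  res <- rbind(fwd, rev)
  if (is.null(res) || !nrow(res))
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resname_b = character(0),
                      min_dist = numeric(0)))
  key <- paste(res$chain_a, res$resno_a, res$chain_b, res$resno_b)
  agg <- res[order(key, res$min_dist), ]
  agg <- agg[!duplicated(paste(agg$chain_a, agg$resno_a, agg$chain_b,
                               agg$resno_b)), ]
  rownames(agg) <- NULL
  agg
}

# Deterministic quasi-uniform unit-sphere point set (golden-spiral /
# Fibonacci lattice), shared by every SASA evaluation at a given n_points.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley solvent-accessible surface area (A^2) of a model.
.sasa <- function(model, probe = 1.4, n_points = 960, radii = NULL) {
  model <- .heavy(model)
  n <- n_atoms(model)
  if (n == 0) return(0)
  xyz <- coords(model)
  re <- vdw_radii(model, radii) + probe
  pts <- .sphere_points(n_points)
  cutoff <- 2 * max(re)
  nb <- .close_pairs(xyz, xyz, cutoff)
  nb_list <- split(nb$j[nb$i != nb$j], nb$i[nb$i != nb$j])
  total <- 0
  for (i in seq_len(n)) {
    surf <- sweep(pts * re[i], 2, xyz[i, ], "+")
    nbrs <- nb_list[[as.character(i)]]
    acc <- rep(TRUE, n_points)
    for (j in nbrs) {
      if (!any(acc)) break
      d2 <- rowSums(sweep(surf[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- d2 > re[j]^2
    }
    total <- total + mean(acc) * 4 * pi * re[i]^2
  }
  total
}

#' Buried (contact) surface area between two models
#'
#' Shrake-Rupley sampling with a deterministic golden-spiral point set:
#' buried area = (SASA(a) + SASA(b) - SASA(a+b)) / 2, i.e. the per-side
#' contact area.  Set `total = TRUE` for the two-sided buried surface.
#'
#' @param a,b structure_model
#' @param probe probe radius, Angstrom (default 1.4, water)
#' @param n_points sphere sample points per atom (default 960)
#' @param total report both sides (default FALSE: per-side)
#' @param radii optional vdW radius table
#' @return area in Angstrom^2
#' @export
buried_area <- function(a, b, probe = 1.4, n_points = 960, total = FALSE,
                        radii = NULL) {
  s_a <- .sasa(a, probe, n_points, radii)
  s_b <- .sasa(b, probe, n_points, radii)
  s_ab <- .sasa(combine_models(a, b), probe, n_points, radii)
  buried <- s_a + s_b - s_ab
  if (total) buried else buried / 2
}
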