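# Point-group operators and the head-tail orientation-mismatch analysis.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; proper rotation (det +1).
#' @param axis length-3 vector (normalized internally)
#' @param angle rotation angle in degrees
#' @return 3 x 3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero-length rotation axis")
  u <- axis / n
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Cyclic point group Cn
#'
#' The n rotations by k * 360/n (k = 0 ... n-1) about `axis`.  Each operator
#' is a list with a 3x3 `matrix` and a 3-vector `translation` (zero here).
#'
#' @param n fold (integer >= 1)
#' @param axis rotation axis, default z
#' @return object of class `symmetry_group` with fields name, axis, ops
#' @export
cyclic_group <- function(n, axis = c(0, 0, 1)) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  axis <- axis / sqrt(sum(axis^2))
  ops <- lapply(seq_len(n) - 1L, function(k)
    list(matrix = rotation_about_axis(axis, k * 360 / n),
         translation = c(0, 0, 0)))
  structure(list(name = paste0("C", n), axis = axis, ops = ops),
            class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("symmetry_group ", x$name, " (", length(x$ops), " ops), axis (",
      paste(signif(x$axis, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Symmetry-expand a structure model
#'
#' Applies every operator of `group` to `model` and concatenates the copies.
#' Copy k (k > 0) carries a "_k" chain-id suffix; copy 0 is the input
#' unchanged.  Output atom count is |ops| x |atoms|.
#'
#' @param model structure_model, non-empty
#' @param group symmetry_group
#' @return structure_model of the expanded assembly
#' @export
expand_assembly <- function(model, group) {
  stopifnot(inherits(model, "structure_model"),
            inherits(group, "symmetry_group"))
  if (n_atoms(model) == 0) stop("cannot expand an empty model")
  xyz <- coords(model)
  copies <- lapply(seq_along(group$ops), function(i) {
    op <- group$ops[[i]]
    at <- model$atoms
    new_xyz <- xyz %*% t(op$matrix) +
      matrix(op$translation, nrow(xyz), 3, byrow = TRUE)
    at$x <- new_xyz[, 1]; at$y <- new_xyz[, 2]; at$z <- new_xyz[, 3]
    if (i > 1) at$chain_id <- paste0(at$chain_id, "_", i - 1L)
    at
  })
  at <- do.call(rbind, copies)
  at$serial <- seq_len(nrow(at))
  structure_model(at, label = paste0(model$label, "_", group$name))
}

#' Euler angles to rotation matrix (intrinsic ZYZ)
#'
#' R = Rz(az) Ry(alt) Rz(phi): first a rotation by phi about z, then alt
#' about the (original) y axis, then az about z.  az is the rotation about
#' the symmetry axis, which makes it the angle degenerate under cyclic
#' symmetry about z.  (0, 0, 0) gives the identity.
#'
#' @param e euler_triple, or anything with fields alt, az, phi (degrees)
#' @return list with `matrix` (3x3) and `translation` (zero 3-vector)
#' @export
euler_to_matrix <- function(e) {
  Rz <- function(a) rotation_about_axis(c(0, 0, 1), a)
  Ry <- function(a) rotation_about_axis(c(0, 1, 0), a)
  list(matrix = Rz(e$az) %*% Ry(e$alt) %*% Rz(e$phi),
       translation = c(0, 0, 0))
}

#' Rotation matrix to Euler angles (intrinsic ZYZ)
#'
#' Inverse of [euler_to_matrix] away from gimbal lock.  At gimbal lock
#' (alt = 0 or 180) the az/phi split is degenerate; the convention here is
#' that phi absorbs the full in-plane angle and az is reported as 0.
#'
#' @param R 3x3 rotation matrix, or a list with a `matrix` field
#' @return euler_triple
#' @export
matrix_to_euler <- function(R) {
  if (is.list(R)) R <- R$matrix
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0)
    stop("input is not a proper rotation matrix")
  c33 <- min(max(R[3, 3], -1), 1)
  alt <- acos(c33) * 180 / pi
  if (abs(c33) > 1 - 1e-12) {
    # gimbal lock: R is a pure rotation about z (times diag(1,1,-1) flip
    # handled by alt = 180); phi absorbs az
    phi <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (c33 < 0) phi <- -phi
    return(euler_triple(alt, 0, phi))
  }
  az <- atan2(R[2, 3], R[1, 3]) * 180 / pi
  phi <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  euler_triple(alt, az, phi)
}

#' Symmetry-equivalent orientations under Cn
#'
#' For a particle with cyclic symmetry about its own z axis, the n
#' equivalent orientations differ only in az: element k has az increased by
#' k * 360/n (wrapped); alt and phi are unchanged.  Element 1 is the input.
#'
#' @param tail euler_triple
#' @param n fold (integer >= 1)
#' @return list of n euler_triple
#' @export
equivalent_orientations <- function(tail, n) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  lapply(seq_len(n) - 1, function(k)
    euler_triple(tail$alt, tail$az + k * 360 / n, tail$phi))
}

#' Minimal azimuth difference under cyclic symmetry
#'
#' The minimum over the n symmetry-equivalent tail orientations of the
#' wrapped absolute azimuth difference to the head orientation.  Always in
#' [0, 180/n].
#'
#' @param head,tail euler_triple (or objects with an `az` field, degrees)
#' @param n fold of the tail's cyclic symmetry
#' @return degrees
#' @export
min_azimuth_diff <- function(head, tail, n) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  k <- seq_len(n) - 1
  min(ang_diff(head$az, tail$az + k * 360 / n))
}

#' Filter orientation pairs on alt/phi agreement
#'
#' Retains exactly the pairs whose |delta alt| and wrapped |delta phi| are
#' both <= `max_dev` degrees; pairs deviating by more than the threshold are
#' treated as misassigned and discarded.
#'
#' @param pairs data.frame with columns particle_id, alt_head, az_head,
#'   phi_head, alt_tail, az_tail, phi_tail (as produced by
#'   [make_orientation_set], or by merging two orientation tables on
#'   particle_id)
#' @param max_dev threshold in degrees (default 5)
#' @return the retained subset of `pairs`
#' @export
filter_orientation_pairs <- function(pairs, max_dev = 5) {
  need <- c("alt_head", "phi_head", "alt_tail", "phi_tail")
  stopifnot(all(need %in% names(pairs)))
  keep <- abs(pairs$alt_head - pairs$alt_tail) <= max_dev &
    ang_diff(pairs$phi_head, pairs$phi_tail) <= max_dev
  pairs[keep, , drop = FALSE]
}

#' Merge head and tail orientation tables into pairs
#'
#' Inner join on particle_id, keeping the head table's row order.
#' @param head,tail orientation data.frames (see [read_orientations])
#' @return pair data.frame suitable for [filter_orientation_pairs]
#' @export
orientation_pairs <- function(head, tail) {
  m <- merge(head, tail, by = "particle_id", sort = FALSE,
             suffixes = c("_head", "_tail"))
  m[, c("particle_id", "alt_head", "az_head", "phi_head",
        "alt_tail", "az_tail", "phi_tail")]
}

#' Head-tail orientation-mismatch summary
#'
#' Computes the minimal azimuth difference (see [min_azimuth_diff]) for each
#' pair, bins the values (default 1-degree bins on [0, 180/n]) and reports a
#' concentration statistic: the fraction of pairs within +/- 2 bin widths of
#' the histogram mode.  A concentration of 1 means all mass sits in one
#' bin-width neighbourhood (a fixed head-tail relationship); assemblies whose
#' symmetry-mismatched component rotates freely give a flat histogram and a
#' low concentration.  The fixed/non-fixed call uses a documented threshold
#' of 0.5 on the concentration.
#'
#' @param pairs pair data.frame (after filtering, >= 1 row)
#' @param n fold of the tail symmetry (12 for a connector dodecamer)
#' @param bin_width histogram bin width in degrees (default 1)
#' @param fixed_threshold concentration above which the relationship is
#'   called fixed (default 0.5)
#' @return list of class `mismatch_summary`: histogram (data.frame mid,
#'   count), min_diffs, concentration, classification
#' @export
mismatch_summary <- function(pairs, n, bin_width = 1, fixed_threshold = 0.5) {
  if (nrow(pairs) < 1) stop("no orientation pairs supplied")
  md <- vapply(seq_len(nrow(pairs)), function(i)
    min_azimuth_diff(list(az = pairs$az_head[i]),
                     list(az = pairs$az_tail[i]), n), numeric(1))
  upper <- 180 / n
  breaks <- seq(0, upper + bin_width, by = bin_width)
  h <- hist(md, breaks = breaks, plot = FALSE, right = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  concentration <- mean(abs(md - mode_mid) <= 2 * bin_width)
  structure(list(
    histogram = data.frame(mid = h$mids, count = h$counts),
    min_diffs = md,
    n_fold = n,
    concentration = concentration,
    classification = if (concentration >= fixed_threshold) "fixed"
    else "non-fixed"),
    class = "mismatch_summary")
}

#' @export
print.mismatch_summary <- function(x, ...) {
  cat(sprintf(
    "mismatch_summary: %d pairs, C%d tail symmetry\n  concentration %.3f -> %s relationship\n",
    length(x$min_diffs), x$n_fold, x$concentration, x$classification))
  invisible(x)
}

#' @export
plot.mismatch_summary <- function(x, ...) {
  barplot(x$histogram$count, names.arg = signif(x$histogram$mid, 3),
          xlab = "minimal azimuth difference (degrees)", ylab = "particles",
          main = sprintf("head-tail azimuth mismatch (%s)", x$classification),
          ...)
  invisible(x)
}
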