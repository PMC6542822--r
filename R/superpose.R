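# Rigid-body superposition and the comparison metrics built on it.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' `ref` and the transformed `mov` (x -> R x + t), via SVD of the covariance
#' matrix with the determinant correction that excludes reflections.
#'
#' @param ref,mov n x 3 coordinate matrices (paired rows), n >= 3,
#'   non-degenerate (not collinear)
#' @return list of class `superposition_result`: rotation (list with
#'   `matrix`, `translation`), rmsd (Angstrom), n_pairs
#' @export
kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3 || ncol(mov) != 3)
    stop("ref and mov must be n x 3 matrices of equal length")
  n <- nrow(ref)
  if (n < 3) stop("at least 3 point pairs are required")
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(mov, 2, cm); B <- sweep(ref, 2, cr)
  if (min(svd(A)$d) < 1e-9 * max(svd(A)$d, 1))
    stop("degenerate (collinear) coordinates: superposition undetermined")
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = list(matrix = R,
                                 translation = as.numeric(cr - R %*% cm)),
                 rmsd = rmsd, n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over %d pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}

#' Apply a rigid transform to a structure model
#' @param model structure_model
#' @param rotation list with `matrix` (3x3) and `translation` (3-vector), as
#'   returned inside a [kabsch] result
#' @return transformed structure_model
#' @export
apply_transform <- function(model, rotation) {
  xyz <- coords(model) %*% t(rotation$matrix)
  xyz <- sweep(xyz, 2, rotation$translation, "+")
  set_coords(model, xyz)
}

# Pair atoms of two models strictly by (chain, residue number, insertion
# code, atom name); errors listing the gaps rather than pairing silently.
.pair_atoms <- function(a, b, ranges = NULL, atom = "CA", chain = NULL) {
  sa <- select_atoms(a, chain = chain, ranges = ranges, atom_name = atom)
  sb <- select_atoms(b, chain = chain, ranges = ranges, atom_name = atom)
  key <- function(m) paste(m$atoms$chain_id, m$atoms$residue_number,
                           m$atoms$insert, m$atoms$atom_name, sep = "|")
  ka <- key(sa); kb <- key(sb)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate (chain, residue, atom) addresses prevent unambiguous pairing")
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  if (length(only_a) || length(only_b))
    stop("unpaired residues/atoms between models:\n  only in first: ",
         paste(utils::head(only_a, 8), collapse = ", "),
         if (length(only_a) > 8) " ...", "\n  only in second: ",
         paste(utils::head(only_b, 8), collapse = ", "),
         if (length(only_b) > 8) " ...")
  idx <- match(ka, kb)
  list(a = coords(sa), b = coords(sb)[idx, , drop = FALSE],
       meta = sa$atoms[, c("chain_id", "residue_number", "insert")])
}

#' Per-range and pooled C-alpha RMSD between two states
#'
#' Pairs atoms strictly by (chain, residue number, insertion code, atom
#' name) over the given residue intervals, then reports RMSD per interval
#' and pooled over their union.  `fit_on` selects the superposition used
#' before measuring: "ranges" fits on the paired range atoms, "whole" fits
#' on all shared atoms of the given name, and "none" measures in the frames
#' as given (for pre-aligned coordinates).
#'
#' @param a,b structure_model
#' @param ranges list of length-2 residue intervals, inclusive (e.g.
#'   `list(c(18, 226), c(248, 284))`)
#' @param atom atom name to pair (default "CA")
#' @param fit_on "ranges", "whole" or "none"
#' @param chain optional chain restriction
#' @return list of class `rmsd_report`: per_range (data.frame start, end,
#'   rmsd, n_pairs), pooled rmsd, n_pairs, fit_on
#' @export
rmsd_ranges <- function(a, b, ranges, atom = "CA",
                        fit_on = c("ranges", "whole", "none"), chain = NULL) {
  fit_on <- match.arg(fit_on)
  if (!is.list(ranges)) ranges <- list(ranges)
  pr <- .pair_atoms(a, b, ranges = ranges, atom = atom, chain = chain)
  xb <- pr$b
  if (fit_on != "none") {
    fit_pairs <- if (fit_on == "ranges") pr else
      .pair_atoms(a, b, ranges = NULL, atom = atom, chain = chain)
    fit <- kabsch(fit_pairs$a, fit_pairs$b)
    xb <- sweep(pr$b %*% t(fit$rotation$matrix), 2,
                fit$rotation$translation, "+")
  }
  dev2 <- rowSums((pr$a - xb)^2)
  resno <- pr$meta$residue_number
  per <- do.call(rbind, lapply(ranges, function(r) {
    in_r <- resno >= r[1] & resno <= r[2]
    data.frame(start = r[1], end = r[2],
               rmsd = sqrt(mean(dev2[in_r])), n_pairs = sum(in_r))
  }))
  structure(list(per_range = per, pooled = sqrt(mean(dev2)),
                 n_pairs = length(dev2), fit_on = fit_on, atom = atom),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("rmsd_report (%s atoms, fit_on = %s)\n", x$atom, x$fit_on))
  print(x$per_range, row.names = FALSE)
  cat(sprintf("pooled: %.3f A over %d pairs\n", x$pooled, x$n_pairs))
  invisible(x)
}

#' Centre-of-gravity displacement in a common capsid frame
#'
#' Measures how far a selected subassembly (e.g. the connector neck) moves
#' between two states of an assembly, after placing both states in a common
#' frame: the frame models (e.g. the two capsids) are superposed by Kabsch
#' on their shared atoms, the resulting transform is applied to state b, and
#' the displacement is COG(selection of a) - COG(transformed selection of
#' b).  The gravity centre is the unweighted mean of the selected atom
#' positions.
#'
#' @param state_a,state_b structure_model of the moving subassembly in the
#'   two states
#' @param frame_a,frame_b structure_model of the reference frames (must
#'   share a common atom set by chain/residue/atom name)
#' @param chain,ranges,atom_name selection applied to both states (see
#'   [select_atoms]); default: all atoms
#' @param frame_atom atom name used for the frame superposition (default
#'   "CA")
#' @return list: vector (3-vector, Angstrom, a relative to b), magnitude
#'   (Angstrom), frame_rmsd of the frame superposition
#' @export
cog_displacement <- function(state_a, state_b, frame_a, frame_b,
                             chain = NULL, ranges = NULL, atom_name = NULL,
                             frame_atom = "CA") {
  sel_a <- select_atoms(state_a, chain = chain, ranges = ranges,
                        atom_name = atom_name)
  sel_b <- select_atoms(state_b, chain = chain, ranges = ranges,
                        atom_name = atom_name)
  if (n_atoms(sel_a) == 0 || n_atoms(sel_b) == 0)
    stop("empty selection in one of the states")
  fp <- .pair_atoms(frame_a, frame_b, atom = frame_atom)
  fit <- kabsch(fp$a, fp$b)
  moved_b <- apply_transform(sel_b, fit$rotation)
  v <- colMeans(coords(sel_a)) - colMeans(coords(moved_b))
  list(vector = as.numeric(v), magnitude = sqrt(sum(v^2)),
       frame_rmsd = fit$rmsd)
}
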