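#' Atomic structure container
#'
#' A `structure_model` is an ordered table of atom records (one row per
#' ATOM/HETATM-style record) plus a free-text label.  Coordinates are in
#' Angstrom throughout the package.  The atom table has the columns
#' `serial`, `atom_name`, `residue_name`, `residue_number`, `insert`,
#' `chain_id`, `element`, `x`, `y`, `z`, `occupancy`, `b_factor`.
#'
#' Atom serials must be unique within a model; selections by chain, residue
#' range and atom name are deterministic and preserve file order.
#'
#' @param atoms data.frame with the columns listed above.  Missing optional
#'   columns (`insert`, `occupancy`, `b_factor`, `serial`) are filled with
#'   defaults.
#' @param label character scalar naming the model.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "model") {
  stopifnot(is.data.frame(atoms))
  required <- c("atom_name", "residue_name", "residue_number", "chain_id",
                "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$insert)) atoms$insert <- rep("", n)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$b_factor)) atoms$b_factor <- rep(0, n)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  atoms$atom_name <- trimws(as.character(atoms$atom_name))
  atoms$residue_name <- trimws(as.character(atoms$residue_name))
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  if (n > 0) {
    if (anyDuplicated(atoms$serial))
      stop("atom serials are not unique")
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      stop("non-finite coordinates in atom table")
    if (any(!nzchar(atoms$element)))
      stop("empty element symbols in atom table")
  }
  atoms <- atoms[, c("serial", "atom_name", "residue_name", "residue_number",
                     "insert", "chain_id", "element", "x", "y", "z",
                     "occupancy", "b_factor")]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = as.character(label)[1]),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  cat("structure_model '", x$label, "': ", nrow(at), " atoms, ",
      length(unique(at$chain_id)), " chain(s)\n", sep = "")
  if (nrow(at)) {
    cat("  chains: ", paste(sort(unique(at$chain_id)), collapse = " "), "\n",
        sep = "")
    rng <- apply(at[, c("x", "y", "z")], 2, range)
    cat(sprintf("  extent: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] A\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model structure_model
#' @return integer atom count
#' @export
n_atoms <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  nrow(model$atoms)
}

#' Coordinate matrix of a structure model
#' @param model structure_model
#' @return numeric n x 3 matrix of x, y, z in Angstrom
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a model
#'
#' Returns a copy of `model` with its coordinate columns replaced; all other
#' atom fields are kept.  Used by the rigid-body operations.
#'
#' @param model structure_model
#' @param xyz n x 3 numeric matrix
#' @return structure_model
#' @export
set_coords <- function(model, xyz) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(model$atoms) || ncol(xyz) != 3)
    stop("coordinate matrix must be n_atoms x 3")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Select atoms by chain, residue range and atom name
#'
#' Conjunctive selection: every supplied condition must hold.  Residue
#' numbering is taken verbatim from the source file (author numbering) and
#' ranges are inclusive on both ends.  Order of the input atoms is preserved,
#' so selections are stable under reordering of unrelated chains.
#'
#' @param model structure_model
#' @param chain character vector of chain ids, or NULL for all
#' @param resno integer vector of residue numbers, or NULL
#' @param ranges list of length-2 integer vectors, residue intervals
#'   (inclusive); combined with `resno` by union
#' @param atom_name character vector of atom names (e.g. "CA"), or NULL
#' @param element character vector of element symbols, or NULL
#' @return structure_model restricted to the matching atoms
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, ranges = NULL,
                         atom_name = NULL, element = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain_id %in% chain
  if (!is.null(ranges)) {
    if (!is.list(ranges)) ranges <- list(ranges)
    in_rng <- rep(FALSE, nrow(at))
    for (r in ranges) {
      stopifnot(length(r) == 2)
      in_rng <- in_rng | (at$residue_number >= r[1] & at$residue_number <= r[2])
    }
    if (!is.null(resno)) in_rng <- in_rng | at$residue_number %in% resno
    keep <- keep & in_rng
  } else if (!is.null(resno)) {
    keep <- keep & at$residue_number %in% resno
  }
  if (!is.null(atom_name)) keep <- keep & at$atom_name %in% atom_name
  if (!is.null(element)) keep <- keep & toupper(at$element) %in% toupper(element)
  structure_model(at[keep, , drop = FALSE], label = model$label)
}

#' Concatenate structure models
#'
#' Atom order follows the argument order; serials are renumbered to stay
#' unique.
#' @param ... structure_model objects
#' @param label label for the combined model
#' @return structure_model
#' @export
combine_models <- function(..., label = "combined") {
  models <- list(...)
  stopifnot(all(vapply(models, inherits, TRUE, "structure_model")))
  at <- do.call(rbind, lapply(models, function(m) m$atoms))
  at$serial <- seq_len(nrow(at))
  structure_model(at, label = label)
}

# Default van der Waals radii (Angstrom), MolProbity-style heavy-atom set.
.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Van der Waals radii for the atoms of a model
#'
#' @param model structure_model
#' @param radii named numeric vector element -> radius (Angstrom); defaults
#'   to C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20
#' @return numeric vector, one radius per atom
#' @export
vdw_radii <- function(model, radii = NULL) {
  if (is.null(radii)) radii <- .default_vdw
  el <- toupper(model$atoms$element)
  r <- radii[el]
  if (anyNA(r)) {
    bad <- sort(unique(el[is.na(r)]))
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

# Simple pseudo-atom builder used by generators and tests: carbons named CA
# unless stated otherwise.
make_model <- function(xyz, chain = "A", resno = NULL, atom_name = "CA",
                       residue_name = "ALA", element = "C", label = "synthetic") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  structure_model(data.frame(
    atom_name = rep_len(atom_name, n),
    residue_name = rep_len(residue_name, n),
    residue_number = rep_len(as.integer(resno), n),
    chain_id = rep_len(chain, n),
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), label = label)
}
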