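#' Read an atomic structure (PDB or mmCIF)
#'
#' Thin wrapper around bio3d's parsers returning a [structure_model].  Every
#' ATOM/HETATM record becomes one atom row, in file order; coordinates are in
#' Angstrom; insertion codes are preserved in residue addressing.
#'
#' @param path file path
#' @param format "pdb", "mmcif", or "auto" (from the file extension)
#' @return structure_model
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer structure format from extension '",
                          ext, "'"))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE, rm.insert = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  element <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                   substr(trimws(at$elety), 1, 1), at$elesy)))
  structure_model(data.frame(
    serial = at$eleno,
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE),
    label = basename(path))
}

#' Write an atomic structure (PDB or mmCIF)
#'
#' PDB output goes through bio3d; mmCIF output writes a minimal `atom_site`
#' category.  Chain ids longer than one character cannot be represented in
#' PDB; they are remapped deterministically (A, B, C, ...) with a warning.
#' Re-reading the written file reproduces the atom list in order, at format
#' precision (1e-3 Angstrom for PDB).
#'
#' @param model structure_model, non-empty
#' @param path output file path
#' @param format "pdb", "mmcif", or "auto" (from the extension)
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(model, "structure_model"))
  format <- match.arg(format)
  if (n_atoms(model) == 0) stop("refusing to write an empty structure_model")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer structure format from extension '",
                          ext, "'"))
  }
  at <- model$atoms
  if (format == "pdb") {
    chain <- at$chain_id
    if (any(nchar(chain) > 1)) {
      uc <- unique(chain)
      pool <- c(LETTERS, letters, 0:9)
      if (length(uc) > length(pool))
        stop("too many chains for PDB output (", length(uc), ")")
      map <- setNames(pool[seq_along(uc)], uc)
      warning("chain ids longer than 1 character remapped for PDB output")
      chain <- unname(map[chain])
    }
    ok <- tryCatch({
      bio3d::write.pdb(file = path,
                       xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                       type = rep("ATOM", nrow(at)),
                       resno = at$residue_number,
                       resid = at$residue_name,
                       eleno = at$serial,
                       elety = at$atom_name,
                       chain = chain,
                       insert = ifelse(nzchar(at$insert), at$insert, NA),
                       o = at$occupancy, b = at$b_factor,
                       elesy = at$element)
      TRUE
    }, error = function(e) stop("cannot write PDB to '", path, "': ",
                                conditionMessage(e)))
  } else {
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot open '", path,
                                             "' for writing"))
    on.exit(close(con))
    # standard RCSB atom_site column order (what mmCIF readers expect)
    writeLines(c(
      paste0("data_", gsub("[^A-Za-z0-9_]", "_", model$label)),
      "#", "loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.label_atom_id", "_atom_site.label_alt_id",
      "_atom_site.label_comp_id", "_atom_site.label_asym_id",
      "_atom_site.label_entity_id", "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
      "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"), con)
    writeLines(sprintf(
      "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      at$serial, at$element, at$atom_name, at$residue_name, at$chain_id,
      at$residue_number, ifelse(nzchar(at$insert), at$insert, "?"),
      at$x, at$y, at$z, at$occupancy, at$b_factor,
      at$residue_number, at$residue_name, at$chain_id, at$atom_name), con)
    writeLines("#", con)
  }
  invisible(path)
}
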