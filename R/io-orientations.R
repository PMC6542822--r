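# Angle helpers: degrees everywhere.

#' Wrap an angle into [0, 360)
#' @param a angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap360 <- function(a) {
  w <- a %% 360
  w[w == 360] <- 0
  w
}

#' Wrapped absolute angular difference
#'
#' min(|a - b| mod 360, 360 - |a - b| mod 360), in degrees; always in
#' [0, 180].
#' @param a,b angles in degrees
#' @return non-negative difference(s)
#' @export
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Canonical Euler triple
#'
#' Orientations are stored as (alt, az, phi) in degrees with alt in [0, 180]
#' and az, phi wrapped into [0, 360).  The rotation convention is intrinsic
#' ZYZ (see [euler_to_matrix]); az is the angle about the symmetry (z) axis
#' and is therefore the angle degenerate under cyclic symmetry.
#'
#' @param alt,az,phi angles in degrees
#' @return list of class `euler_triple`
#' @export
euler_triple <- function(alt, az, phi) {
  alt <- as.numeric(alt); az <- as.numeric(az); phi <- as.numeric(phi)
  if (alt < -1e-9 || alt > 180 + 1e-9)
    stop("alt must lie in [0, 180] degrees, got ", alt)
  structure(list(alt = min(max(alt, 0), 180), az = wrap360(az),
                 phi = wrap360(phi)), class = "euler_triple")
}

#' Read a per-particle orientation table
#'
#' Whitespace- or comma-delimited text with a header naming at least
#' `particle_id`, `alt`, `az` and `phi` (any column order; angles in
#' degrees).  Angles are wrapped to canonical ranges on read: az and phi into
#' [0, 360); alt must already lie in [0, 180].
#'
#' @param path file path
#' @return data.frame with columns particle_id, alt, az, phi
#' @export
read_orientations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           strip.white = TRUE, comment.char = "#")
  need <- c("particle_id", "alt", "az", "phi")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("orientation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[, need, drop = FALSE]
  if (nrow(tab) == 0) return(tab)
  for (col in c("alt", "az", "phi")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric ", col, " at data row ", bad,
           " (file line ", bad + 1, ")")
    }
    tab[[col]] <- v
  }
  if (any(tab$alt < -1e-9 | tab$alt > 180 + 1e-9))
    stop("alt values outside [0, 180] degrees")
  tab$alt <- pmin(pmax(tab$alt, 0), 180)
  tab$az <- wrap360(tab$az)
  tab$phi <- wrap360(tab$phi)
  tab$particle_id <- as.character(tab$particle_id)
  tab
}

#' Write an orientation table as tab-separated text
#' @param tab data.frame with particle_id, alt, az, phi
#' @param path output path
#' @return `path`, invisibly
#' @export
write_orientations <- function(tab, path) {
  stopifnot(all(c("particle_id", "alt", "az", "phi") %in% names(tab)))
  utils::write.table(tab[, c("particle_id", "alt", "az", "phi")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
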