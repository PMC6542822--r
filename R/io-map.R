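#' Density grid container
#'
#' A 3D scalar field with isotropic voxel size (Angstrom per voxel) and an
#' origin giving the position, in Angstrom, of the first voxel's corner.
#' Values are stored x-fastest (the canonical axis order of this package).
#'
#' @param values numeric 3D array
#' @param voxel voxel size in Angstrom (> 0, isotropic)
#' @param origin length-3 numeric, Angstrom
#' @return object of class `density_grid`
#' @export
density_grid <- function(values, voxel, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.numeric(voxel) || length(voxel) != 1 || voxel <= 0)
    stop("voxel size must be a single positive number")
  if (!all(is.finite(values))) stop("density values must be finite")
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(values = values, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid %d x %d x %d, voxel %.4f A, origin (%.2f, %.2f, %.2f) A\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values: min %.4g  max %.4g  mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# MRC/CCP4 2014 header layout constants (1024-byte header, mode 2 float32).
.mrc_header_words <- 256

#' Read an MRC/CCP4 2014 density map
#'
#' Supports mode 2 (float32) and mode 0 (int8) maps with orthogonal cells.
#' The axis order is normalized to x-fastest on read using the mapc/mapr/maps
#' header words.  Voxel size is taken from the cell dimensions divided by the
#' sampling (mx, my, mz) and must be isotropic within 0.1%, otherwise an
#' error is raised.
#'
#' @param path file path
#' @return density_grid
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]; mode <- hdr_i[4]
  if (!(mode %in% c(0, 2)))
    stop("unsupported MRC mode ", mode, " (only 0 and 2 are read)")
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) > 1e4))
    stop("implausible MRC dimensions; wrong endianness or corrupt header")
  mxyz <- hdr_i[8:10]                                     # words 8-10
  cell <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  angs <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(abs(angs - 90) > 1e-3))
    stop("non-orthogonal cells are not supported (angles ",
         paste(round(angs, 2), collapse = ", "), ")")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg, nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra (25-49)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  n_total <- nx * ny * nz
  values <- if (mode == 2)
    readBin(con, "numeric", n = n_total, size = 4, endian = "little")
  else
    as.numeric(readBin(con, "integer", n = n_total, size = 1, signed = TRUE))
  if (length(values) < n_total) stop("truncated MRC data block in ", path)
  vox3 <- cell / mxyz
  if (max(vox3) - min(vox3) > 1e-3 * mean(vox3))
    stop("anisotropic voxel size (", paste(signif(vox3, 6), collapse = ", "),
         "); only isotropic maps are supported")
  arr <- array(values, dim = c(nx, ny, nz))
  # normalize axis order: column c of the file corresponds to axis mapcrs[c]
  if (!identical(mapcrs, 1:3)) {
    if (!setequal(mapcrs, 1:3)) stop("invalid mapc/mapr/maps in header")
    arr <- aperm(arr, order(mapcrs))
    origin <- origin  # origin words are already in x,y,z order per MRC2014
  }
  density_grid(arr, voxel = mean(vox3), origin = origin)
}

#' Write a density grid as an MRC/CCP4 2014 map
#'
#' Mode 2 (float32), x-fastest axis order, orthogonal unit cell, origin in
#' the MRC2014 origin words.
#'
#' @param grid density_grid
#' @param path output path
#' @return `path`, invisibly
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing"))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2)                      # nx,ny,nz, mode
  wi(c(0, 0, 0))                    # nxstart
  wi(d)                             # mx,my,mz
  wf(d * grid$voxel)                # cell lengths
  wf(c(90, 90, 90))                 # cell angles
  wi(1:3)                           # mapc, mapr, maps
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))    # dmin, dmax, dmean
  wi(c(1, 0))                       # ispg, nsymbt
  wi(rep(0L, 25))                   # extra (words 25-49)
  wf(grid$origin)                   # MRC2014 origin (A)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(v)))       # rms
  wi(0)                             # nlabl
  writeBin(raw(800), con)           # labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}
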