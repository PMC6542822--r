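# Density-grid computations: rasterization, Fourier shell correlation,
# map-model correlation, magnification (pixel-size) calibration, and local
# n-fold density averaging.

.atomic_number <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

# voxel index (1-based) i maps to position origin + (i - 1) * voxel
.grid_positions <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$voxel,
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$voxel,
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$voxel)
}

#' Rasterize an atomic model into a density grid
#'
#' Sum of spherical Gaussians centred on the atoms, one per atom, with
#' amplitude proportional to the atomic number and width sigma (default
#' 1.0 x voxel).  This is a smooth stand-in for an electron-scattering
#' model, adequate for correlation-based comparisons.  Deterministic.
#'
#' @param model structure_model
#' @param voxel voxel size, Angstrom
#' @param dims grid dimensions (nx, ny, nz)
#' @param origin position of voxel (1,1,1), Angstrom; default centres the
#'   grid on the coordinate origin
#' @param sigma Gaussian width, Angstrom (default = voxel)
#' @param clip if FALSE (default), atoms outside the grid raise an error;
#'   if TRUE their out-of-grid density is silently truncated
#' @return density_grid
#' @export
rasterize <- function(model, voxel, dims, origin = NULL, sigma = NULL,
                      clip = FALSE) {
  stopifnot(inherits(model, "structure_model"), voxel > 0,
            length(dims) == 3, all(dims >= 1))
  dims <- as.integer(dims)
  if (is.null(origin)) origin <- -(dims - 1) * voxel / 2
  if (is.null(sigma)) sigma <- voxel
  vals <- array(0, dim = dims)
  if (n_atoms(model) == 0)
    return(density_grid(vals, voxel, origin))
  xyz <- coords(model)
  el <- toupper(model$atoms$element)
  z_num <- .atomic_number[el]
  if (anyNA(z_num))
    stop("no atomic number for element(s): ",
         paste(unique(el[is.na(z_num)]), collapse = ", "))
  gp <- list(x = origin[1] + (seq_len(dims[1]) - 1) * voxel,
             y = origin[2] + (seq_len(dims[2]) - 1) * voxel,
             z = origin[3] + (seq_len(dims[3]) - 1) * voxel)
  lo <- origin; hi <- origin + (dims - 1) * voxel
  inside <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  if (!clip && any(!inside))
    stop(sum(!inside), " atom(s) fall outside the grid (use clip = TRUE ",
         "to truncate)")
  reach <- 5 * sigma
  s2 <- 2 * sigma^2
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    ix <- which(abs(gp$x - p[1]) <= reach)
    iy <- which(abs(gp$y - p[2]) <= reach)
    iz <- which(abs(gp$z - p[3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    wx <- exp(-(gp$x[ix] - p[1])^2 / s2)
    wy <- exp(-(gp$y[iy] - p[2])^2 / s2)
    wz <- exp(-(gp$z[iz] - p[3])^2 / s2)
    block <- z_num[i] * outer(wx, wy)
    for (k in seq_along(iz))
      vals[ix, iy, iz[k]] <- vals[ix, iy, iz[k]] + block * wz[k]
  }
  density_grid(vals, voxel, origin)
}

#' Fourier shell correlation between two maps
#'
#' Normalized cross-correlation of the Fourier coefficients of the two maps
#' per resolution shell (shell width = one Fourier voxel), with the
#' resolution reported at the first downward crossing of the gold-standard
#' 0.143 threshold (linear interpolation between shells).
#'
#' @param a,b density_grid with identical dims and voxel size
#' @param threshold resolution criterion (default 0.143)
#' @return list of class `fsc_curve`: shell_freqs (1/Angstrom),
#'   correlations, resolution_at_threshold (Angstrom; NA if the curve never
#'   drops below the threshold)
#' @export
fsc <- function(a, b, threshold = 0.143) {
  stopifnot(inherits(a, "density_grid"), inherits(b, "density_grid"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids have different dimensions")
  if (abs(a$voxel - b$voxel) > 1e-6 * a$voxel)
    stop("grids have different voxel sizes")
  d <- dim(a$values)
  fa <- fft(a$values); fb <- fft(b$values)
  freq_axis <- function(n) {
    k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
    k / n
  }
  kx <- freq_axis(d[1]); ky <- freq_axis(d[2]); kz <- freq_axis(d[3])
  # |k| in 1/Angstrom on the full 3D grid
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  kabs <- sqrt(k2) / a$voxel
  df <- 1 / (max(d) * a$voxel)          # shell width, one Fourier voxel
  shell <- as.integer(round(kabs / df))
  n_shell <- floor(max(d) / 2)
  keep <- shell >= 1 & shell <= n_shell & kabs <= 0.5 / a$voxel
  sh <- shell[keep]
  num <- tapply(Re(fa[keep] * Conj(fb[keep])), sh, sum)
  da <- tapply(abs(fa[keep])^2, sh, sum)
  db <- tapply(abs(fb[keep])^2, sh, sum)
  corr <- as.numeric(num / sqrt(da * db))
  shells <- as.integer(names(num))
  freqs <- shells * df
  nvox <- as.numeric(tapply(rep(1, sum(keep)), sh, sum))
  res <- NA_real_
  below <- which(corr < threshold)
  if (length(below)) {
    i <- below[1]
    if (i == 1) res <- 1 / freqs[1]
    else {
      f <- freqs[i - 1] + (threshold - corr[i - 1]) *
        (freqs[i] - freqs[i - 1]) / (corr[i] - corr[i - 1])
      res <- 1 / f
    }
  }
  structure(list(shell_freqs = freqs, correlations = corr,
                 shell_voxels = nvox, threshold = threshold,
                 resolution_at_threshold = res),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells to %.3f 1/A\n", length(x$shell_freqs),
              max(x$shell_freqs)))
  if (is.na(x$resolution_at_threshold))
    cat(sprintf("  no crossing of FSC = %.3f within Nyquist\n", x$threshold))
  else
    cat(sprintf("  resolution at FSC = %.3f: %.2f A\n", x$threshold,
                x$resolution_at_threshold))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  plot(x$shell_freqs, x$correlations, type = "l",
       xlab = "spatial frequency (1/A)", ylab = "FSC", ylim = c(-0.2, 1), ...)
  abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Map-model correlation
#'
#' Normalized cross-correlation between a density grid and the rasterization
#' of a model on the same grid, over all Fourier components to Nyquist
#' (equivalently, by Parseval, the Pearson correlation of the mean-removed
#' real-space values).  Value in [-1, 1].
#'
#' @param grid density_grid
#' @param model structure_model
#' @param sigma rasterization width (default: grid voxel size)
#' @param clip passed to [rasterize]
#' @return numeric correlation coefficient
#' @export
map_model_cc <- function(grid, model, sigma = NULL, clip = FALSE) {
  stopifnot(inherits(grid, "density_grid"))
  r <- rasterize(model, voxel = grid$voxel, dims = dim(grid$values),
                 origin = grid$origin, sigma = sigma, clip = clip)
  if (stats::sd(grid$values) == 0 || stats::sd(r$values) == 0) return(0)
  stats::cor(as.vector(grid$values), as.vector(r$values))
}

#' Magnification (pixel-size) calibration by CC sweep
#'
#' Estimates the true pixel size of a map by relabelling its voxel size with
#' a series of trial values, recomputing the map-model correlation against a
#' fixed reference model at each trial value, and fitting a quadratic to the
#' five points bracketing the maximum of the CC-pixel curve; the vertex of
#' the fit is the calibrated pixel value.  The grid's origin is rescaled
#' proportionally with the trial pixel (origin is held fixed in voxel
#' units).  If the CC maximum falls on a sweep boundary the result is
#' flagged and a warning emitted rather than extrapolating.
#'
#' @param grid density_grid whose nominal voxel size is suspect
#' @param ref_model reference structure of known geometry, in the map's
#'   coordinate frame
#' @param pixel_min,pixel_max sweep range, Angstrom/pixel (must bracket the
#'   nominal value)
#' @param n_steps number of trial pixel values (default 31)
#' @param sigma rasterization width in voxel units (default 1; the Gaussian
#'   width scales with the trial pixel)
#' @return list of class `calib_result`: pixel_values, cc_values,
#'   calibrated_pixel, fit_coefficients, boundary (logical)
#' @export
calibrate_pixel <- function(grid, ref_model, pixel_min, pixel_max,
                            n_steps = 31, sigma = 1) {
  stopifnot(inherits(grid, "density_grid"), pixel_min > 0,
            pixel_max > pixel_min, n_steps >= 5)
  nominal <- grid$voxel
  if (nominal < pixel_min || nominal > pixel_max)
    stop("sweep range must bracket the nominal pixel value ", nominal)
  trial <- seq(pixel_min, pixel_max, length.out = n_steps)
  d <- dim(grid$values)
  cc <- vapply(trial, function(p) {
    r <- rasterize(ref_model, voxel = p, dims = d,
                   origin = grid$origin * (p / nominal), sigma = sigma * p,
                   clip = TRUE)
    stats::cor(as.vector(grid$values), as.vector(r$values))
  }, numeric(1))
  imax <- which.max(cc)
  boundary <- imax <= 2 || imax >= n_steps - 1
  if (boundary) {
    warning("CC maximum at sweep boundary; calibrated pixel unreliable")
    calibrated <- trial[imax]
    fit <- NULL
  } else {
    idx <- max(1, imax - 2):min(n_steps, imax + 2)
    fit <- stats::lm(cc[idx] ~ poly(trial[idx], 2, raw = TRUE))
    co <- stats::coef(fit)
    calibrated <- -co[2] / (2 * co[3])
    calibrated <- min(max(calibrated, pixel_min), pixel_max)
  }
  structure(list(pixel_values = trial, cc_values = cc,
                 calibrated_pixel = as.numeric(calibrated),
                 fit_coefficients = if (is.null(fit)) NULL
                 else unname(stats::coef(fit)),
                 boundary = boundary),
            class = "calib_result")
}

#' @export
print.calib_result <- function(x, ...) {
  cat(sprintf("calib_result: sweep %.4f - %.4f A/pixel (%d steps)\n",
              min(x$pixel_values), max(x$pixel_values),
              length(x$pixel_values)))
  cat(sprintf("  calibrated pixel: %.4f A%s\n", x$calibrated_pixel,
              if (x$boundary) " [boundary - unreliable]" else ""))
  invisible(x)
}

#' @export
plot.calib_result <- function(x, ...) {
  plot(x$pixel_values, x$cc_values, type = "b",
       xlab = "trial pixel (A)", ylab = "map-model CC", ...)
  abline(v = x$calibrated_pixel, lty = 2)
  invisible(x)
}

# Trilinear interpolation of a grid at arbitrary positions (n x 3, Angstrom);
# positions outside the grid evaluate to 0.
.interp_trilinear <- function(grid, pos) {
  d <- dim(grid$values)
  f <- sweep(pos, 2, grid$origin) / grid$voxel + 1  # fractional 1-based index
  i0 <- floor(f)
  t <- f - i0
  out <- numeric(nrow(pos))
  v <- grid$values
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
    w <- (if (cx) t[, 1] else 1 - t[, 1]) *
      (if (cy) t[, 2] else 1 - t[, 2]) *
      (if (cz) t[, 3] else 1 - t[, 3])
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3] &
      w > 0
    if (any(ok))
      out[ok] <- out[ok] + w[ok] * v[cbind(ii[ok], jj[ok], kk[ok])]
  }
  out
}

#' Local n-fold symmetry averaging of a density map
#'
#' Averages the density over the n rotations about `axis` through `point`,
#' inside a spherical mask of radius `mask_radius` centred on `point`;
#' voxels outside the mask are returned unchanged.  Interpolation is
#' trilinear, so the operation is idempotent only to interpolation
#' tolerance.
#'
#' @param grid density_grid
#' @param n fold (integer >= 2)
#' @param axis rotation axis direction
#' @param point centre of the mask and a point on the axis (Angstrom)
#' @param mask_radius Angstrom; the mask sphere must lie inside the grid
#' @return density_grid
#' @export
local_symmetry_average <- function(grid, n, axis = c(0, 0, 1),
                                   point = c(0, 0, 0), mask_radius) {
  stopifnot(inherits(grid, "density_grid"))
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2")
  d <- dim(grid$values)
  lo <- grid$origin; hi <- grid$origin + (d - 1) * grid$voxel
  if (any(point - mask_radius < lo) || any(point + mask_radius > hi))
    stop("mask sphere extends outside the grid")
  gp <- .grid_positions(grid)
  idx <- which(outer(outer((gp$x - point[1])^2, (gp$y - point[2])^2, "+"),
                     (gp$z - point[3])^2, "+") <= mask_radius^2)
  ijk <- arrayInd(idx, d)
  pos <- cbind(gp$x[ijk[, 1]], gp$y[ijk[, 2]], gp$z[ijk[, 3]])
  centered <- sweep(pos, 2, point)
  acc <- numeric(length(idx))
  for (k in seq_len(n) - 1) {
    R <- rotation_about_axis(axis, k * 360 / n)
    rp <- sweep(centered %*% t(R), 2, point, "+")
    acc <- acc + .interp_trilinear(grid, rp)
  }
  out <- grid$values
  out[idx] <- acc / n
  density_grid(out, grid$voxel, grid$origin)
}
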