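# Steric clash counting and the rotational symmetry-mismatch scan: rotate a
# mobile assembly (the connector) about a symmetry axis inside a fixed
# assembly (the capsid vertex), scoring van der Waals overlaps at each step.

#' Clash-scoring parameters
#'
#' A bad overlap between heavy atoms i, j is (r_i + r_j - d) >=
#' `overlap_threshold` (boundary inclusive), with van der Waals radii per
#' element.  The defaults follow the MolProbity convention: C 1.70, N 1.55,
#' O 1.52, S 1.80, P 1.80 Angstrom and a 0.4 Angstrom overlap threshold;
#' hydrogens are excluded.
#'
#' @param radii named vector element -> radius (Angstrom)
#' @param overlap_threshold Angstrom, >= 0
#' @return list of class `clash_params`
#' @export
clash_params <- function(radii = c(C = 1.70, N = 1.55, O = 1.52,
                                   S = 1.80, P = 1.80),
                         overlap_threshold = 0.4) {
  stopifnot(all(radii > 0), overlap_threshold >= 0)
  structure(list(radii = radii, overlap_threshold = overlap_threshold),
            class = "clash_params")
}

.heavy <- function(model) select_atoms(model, element = setdiff(
  unique(toupper(model$atoms$element)), "H"))

# Candidate close pairs between two coordinate sets via spatial hashing
# (cell lists); returns pairs with distance <= cutoff.  The result is
# defined pair-exhaustively; the hash only prunes.
.close_pairs <- function(xa, xb, cutoff) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0 || nb == 0)
    return(list(i = integer(0), j = integer(0), d = numeric(0)))
  cell <- max(cutoff, 1e-6)
  key <- function(m) {
    g <- floor(m / cell)
    paste(g[, 1], g[, 2], g[, 3], sep = ",")
  }
  cells_b <- split(seq_len(nb), key(xb))
  gb_a <- floor(xa / cell)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- integer(0); jj <- integer(0)
  for (o in seq_len(nrow(offs))) {
    g <- sweep(gb_a, 2, offs[o, ], "+")
    k <- paste(g[, 1], g[, 2], g[, 3], sep = ",")
    hit <- match(k, names(cells_b))
    sel <- which(!is.na(hit))
    if (!length(sel)) next
    lens <- lengths(cells_b)[hit[sel]]
    ii <- c(ii, rep(sel, lens))
    jj <- c(jj, unlist(cells_b[hit[sel]], use.names = FALSE))
  }
  if (!length(ii)) return(list(i = integer(0), j = integer(0), d = numeric(0)))
  d <- sqrt(rowSums((xa[ii, , drop = FALSE] - xb[jj, , drop = FALSE])^2))
  keep <- d <= cutoff
  list(i = ii[keep], j = jj[keep], d = d[keep])
}

#' Count bad van der Waals overlaps between two models
#'
#' Number of inter-model heavy-atom pairs whose van der Waals interpenetration
#' (r_i + r_j - d) reaches the overlap threshold; each pair is counted once.
#' Hydrogens are ignored.  Symmetric in its two model arguments.
#'
#' @param a,b structure_model
#' @param params clash_params
#' @return integer overlap count
#' @export
count_bad_overlaps <- function(a, b, params = clash_params()) {
  a <- .heavy(a); b <- .heavy(b)
  ra <- vdw_radii(a, params$radii); rb <- vdw_radii(b, params$radii)
  cutoff <- max(ra, 0) + max(rb, 0) - params$overlap_threshold + 1e-6
  cp <- .close_pairs(coords(a), coords(b), cutoff)
  if (!length(cp$i)) return(0L)
  overlap <- ra[cp$i] + rb[cp$j] - cp$d
  sum(overlap >= params$overlap_threshold - 1e-9)
}

#' MolProbity-style clashscore of a mobile model against a fixed one
#'
#' 1000 x (number of bad overlaps) / (number of heavy atoms of the mobile
#' model `a`).  The mobile-atom denominator reflects that the scan scores
#' placements of the mobile assembly; pass `denominator = "union"` to
#' normalize by both models' atoms instead.
#'
#' @param a mobile structure_model (non-empty)
#' @param b fixed structure_model
#' @param params clash_params
#' @param denominator "mobile" (default) or "union"
#' @return numeric clashscore (0 when there are no overlaps)
#' @export
clashscore <- function(a, b, params = clash_params(),
                       denominator = c("mobile", "union")) {
  denominator <- match.arg(denominator)
  if (n_atoms(a) == 0) stop("empty mobile model")
  n <- n_atoms(.heavy(a)) +
    if (denominator == "union") n_atoms(.heavy(b)) else 0L
  1000 * count_bad_overlaps(a, b, params) / n
}

#' Rotational clash scan about a symmetry axis
#'
#' Rotates the mobile assembly about `axis` in steps of `step` degrees over
#' `span` degrees, recording at each angle the clashscore against the fixed
#' assembly and the minimum pairwise distance between two named atom
#' selections (e.g. the 12 Tyr122 CA atoms of a connector and the 5 Trp156
#' CA atoms of the capsid).  For a mobile assembly with Cn symmetry about
#' its own axis the curves are periodic with period 360/n.
#'
#' @param mobile,fixed structure_model
#' @param axis rotation axis direction (unit vector; normalized internally)
#' @param point a point on the axis; default: the mobile model's centroid
#'   projected onto the axis direction through the origin
#' @param step angular step, degrees (> 0; default 1)
#' @param span total scanned range, degrees (default 360)
#' @param params clash_params
#' @param sel_mobile,sel_fixed named lists of [select_atoms] arguments for
#'   the minimum-distance curve (e.g. `list(resno = 122, atom_name = "CA")`);
#'   NULL disables the distance curve
#' @param denominator passed to [clashscore]
#' @return object of class `clash_scan`: data.frame-like with angle,
#'   clashscore, min_distance
#' @export
rotational_scan <- function(mobile, fixed, axis = c(0, 0, 1), point = NULL,
                            step = 1, span = 360, params = clash_params(),
                            sel_mobile = NULL, sel_fixed = NULL,
                            denominator = "mobile") {
  if (step <= 0) stop("step must be positive")
  if (sqrt(sum(axis^2)) < 1e-12) stop("zero-length axis")
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(point)) {
    ctr <- colMeans(coords(mobile))
    point <- sum(ctr * axis) * axis
  }
  mob_h <- .heavy(mobile)
  fix_h <- .heavy(fixed)
  r_mob <- vdw_radii(mob_h, params$radii)
  r_fix <- vdw_radii(fix_h, params$radii)
  cutoff <- max(r_mob) + max(r_fix) - params$overlap_threshold + 1e-6
  n_mob <- n_atoms(mob_h) +
    if (denominator == "union") n_atoms(fix_h) else 0L
  x_mob0 <- sweep(coords(mob_h), 2, point)
  x_fix <- coords(fix_h)
  dist_curve <- !is.null(sel_mobile) && !is.null(sel_fixed)
  if (dist_curve) {
    xm_sel0 <- sweep(coords(do.call(select_atoms, c(list(mobile), sel_mobile))),
                     2, point)
    xf_sel <- coords(do.call(select_atoms, c(list(fixed), sel_fixed)))
    if (nrow(xm_sel0) == 0 || nrow(xf_sel) == 0)
      stop("empty min-distance selection")
  }
  angles <- seq(0, span - step, by = step)
  cs <- numeric(length(angles)); md <- rep(NA_real_, length(angles))
  for (t in seq_along(angles)) {
    R <- rotation_about_axis(axis, angles[t])
    xm <- sweep(x_mob0 %*% t(R), 2, point, "+")
    cp <- .close_pairs(xm, x_fix, cutoff)
    n_bad <- if (length(cp$i))
      sum(r_mob[cp$i] + r_fix[cp$j] - cp$d >= params$overlap_threshold - 1e-9)
    else 0L
    cs[t] <- 1000 * n_bad / n_mob
    if (dist_curve) {
      xs <- sweep(xm_sel0 %*% t(R), 2, point, "+")
      md[t] <- sqrt(max(0, min(outer(rowSums(xs^2), rowSums(xf_sel^2), "+") -
                                 2 * xs %*% t(xf_sel))))
    }
  }
  structure(list(angles = angles, clashscores = cs, min_distances = md,
                 step = step, span = span, axis = axis, point = point),
            class = "clash_scan")
}

#' @export
print.clash_scan <- function(x, ...) {
  cat(sprintf("clash_scan: %d angles (step %g deg), clashscore range [%g, %g]\n",
              length(x$angles), x$step, min(x$clashscores),
              max(x$clashscores)))
  if (!all(is.na(x$min_distances)))
    cat(sprintf("  min distance range [%.2f, %.2f] A\n",
                min(x$min_distances), max(x$min_distances)))
  invisible(x)
}

#' @export
plot.clash_scan <- function(x, ...) {
  op <- par(mar = c(5, 4, 2, 4)); on.exit(par(op))
  plot(x$angles, x$clashscores, type = "l", col = "blue",
       xlab = "rotation (degrees)", ylab = "clashscore", ...)
  if (!all(is.na(x$min_distances))) {
    par(new = TRUE)
    plot(x$angles, x$min_distances, type = "l", lty = 2, col = "red",
         axes = FALSE, xlab = "", ylab = "")
    axis(4); mtext("min distance (A)", side = 4, line = 2.5)
  }
  invisible(x)
}

#' Permitted angular windows of a clash scan
#'
#' Maximal contiguous angle intervals where the clashscore is <= `clash_max`
#' and (if a distance curve is present) the minimum distance is >=
#' `dist_min`.  Windows wrapping around the end of a full-circle scan are
#' merged.  Window width is (number of grid angles in the window) x step,
#' and end = start + width.
#'
#' @param scan clash_scan
#' @param clash_max maximum allowed clashscore (default 0)
#' @param dist_min minimum allowed selection distance in Angstrom (default
#'   -Inf, i.e. ignored)
#' @return data.frame with start, end, width (degrees)
#' @export
allowed_windows <- function(scan, clash_max = 0, dist_min = -Inf) {
  stopifnot(inherits(scan, "clash_scan"))
  ok <- scan$clashscores <= clash_max
  if (is.finite(dist_min)) {
    if (all(is.na(scan$min_distances)))
      stop("scan has no min-distance curve to apply dist_min to")
    ok <- ok & scan$min_distances >= dist_min
  }
  n <- length(ok)
  if (!any(ok)) return(data.frame(start = numeric(0), end = numeric(0),
                                  width = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(s = starts[r$values], e = ends[r$values])
  full_circle <- abs(scan$span - 360) < 1e-9
  if (full_circle && nrow(runs) > 1 && runs$s[1] == 1 && runs$e[nrow(runs)] == n) {
    # merge the wrap-around pair
    runs$s[1] <- runs$s[nrow(runs)] - n
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  width <- (runs$e - runs$s + 1) * scan$step
  start <- wrap360((runs$s - 1) * scan$step)
  data.frame(start = start, end = start + width, width = width)
}
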