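## Synthetic ground-truth scenes: fluorophore density maps on a fine grid.
## Beads are rendered as uniform disks with sub-pixel (anti-aliased) edges
## and unit integrated density per bead, so `photons_scale` in the imaging
## module is "expected photons per bead per frame at unit illumination".

#' @keywords internal
new_scene <- function(density, dx_f, meta = list()) {
  stopifnot(all(density >= 0), all(is.finite(density)))
  structure(list(density = density, dx_f = dx_f, meta = meta),
            class = "scene")
}

## Add one disk of given diameter and unit integrated density at (cx, cy)
## [nm, scene coordinates with (0,0) at the grid corner pixel center].
#' @keywords internal
add_bead <- function(density, dx_f, cx, cy, diameter) {
  n1 <- nrow(density); n2 <- ncol(density)
  x <- (0:(n1 - 1L)) * dx_f
  y <- (0:(n2 - 1L)) * dx_f
  r <- sqrt(outer((x - cx)^2, (y - cy)^2, "+"))
  ## sub-pixel anti-aliased edge: linear coverage ramp one pixel wide
  cov <- pmin(1, pmax(0, (diameter / 2 - r) / dx_f + 0.5))
  s <- sum(cov)
  if (s == 0) stop("bead at (", cx, ", ", cy, ") nm falls outside the grid")
  density + cov / s
}

#' Two-bead test scene
#'
#' Two beads of the given diameter with centers separated by exactly
#' `separation` along x, centered in the grid. Each bead carries unit
#' integrated density.
#'
#' @param separation center-to-center distance [nm], > 0
#' @param diameter bead diameter [nm], default 46
#' @param dx_f fine-grid pixel size [nm], default 5
#' @param n grid size [pixels]
#' @return a `scene`
#' @examples
#' sc <- two_bead_scene(40, n = 128)
#' @export
two_bead_scene <- function(separation, diameter = 46, dx_f = 5, n = 208) {
  if (separation <= 0) stop("separation must be > 0")
  extent <- (n - 1) * dx_f
  if (separation + diameter >= extent)
    stop("separation + diameter exceeds the grid extent")
  cx <- extent / 2
  d <- matrix(0, n, n)
  d <- add_bead(d, dx_f, cx - separation / 2, cx, diameter)
  d <- add_bead(d, dx_f, cx + separation / 2, cx, diameter)
  new_scene(d, dx_f, meta = list(kind = "two_beads", separation = separation,
                                 diameter = diameter,
                                 centers = cbind(
                                   x = c(cx - separation / 2,
                                         cx + separation / 2),
                                   y = c(cx, cx))))
}

#' Bead cluster scene
#'
#' One bead per supplied position. The default layout is four beads whose
#' closest pair is 80 nm apart. Overlapping beads are allowed (warning).
#'
#' @param positions two-column matrix of (x, y) bead centers [nm]; NULL for
#'   the default four-bead layout centered in the grid
#' @param diameter bead diameter [nm]
#' @param dx_f fine pixel size [nm]
#' @param n grid size [pixels]
#' @return a `scene`
#' @export
bead_cluster_scene <- function(positions = NULL, diameter = 46, dx_f = 5,
                               n = 208) {
  extent <- (n - 1) * dx_f
  if (is.null(positions)) {
    c0 <- extent / 2
    ## four beads, closest pair 80 nm (the two left-most), others >= 150 nm
    positions <- rbind(c(c0 - 40, c0 - 40), c(c0 + 40, c0 - 40),
                       c(c0 - 90, c0 + 110), c(c0 + 120, c0 + 90))
  }
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 1, ncol(positions) == 2)
  dmat <- as.matrix(stats::dist(positions))
  diag(dmat) <- Inf
  if (nrow(positions) > 1 && min(dmat) < diameter)
    warning("beads overlap (closest centers ", round(min(dmat), 1), " nm)")
  d <- matrix(0, n, n)
  for (i in seq_len(nrow(positions)))
    d <- add_bead(d, dx_f, positions[i, 1L], positions[i, 2L], diameter)
  new_scene(d, dx_f, meta = list(kind = "bead_cluster",
                                 positions = positions, diameter = diameter))
}

#' Random quantum-dot scene
#'
#' Poisson-distributed point emitters (expected count = density x area)
#' rasterized as small disks. Deterministic given `seed`.
#'
#' @param density emitters per square micron, > 0
#' @param seed RNG seed
#' @param dx_f fine pixel size [nm]
#' @param n grid size [pixels]
#' @param diameter emitter diameter [nm], default 10 (sub-pixel dot)
#' @return a `scene`
#' @export
qdot_scene <- function(density, seed = 1, dx_f = 5, n = 208, diameter = 10) {
  stopifnot(density > 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  extent <- (n - 1) * dx_f
  area_um2 <- (extent / 1000)^2
  m <- stats::rpois(1, density * area_um2)
  d <- matrix(0, n, n)
  if (m > 0) {
    xs <- stats::runif(m, 0, extent)
    ys <- stats::runif(m, 0, extent)
    for (i in seq_len(m)) d <- add_bead(d, dx_f, xs[i], ys[i], diameter)
  }
  new_scene(d, dx_f, meta = list(kind = "qdots", density = density,
                                 count = m, seed = seed))
}

#' Random filament scene
#'
#' Smooth random curvilinear filaments (cubic-spline paths through random
#' waypoints) rasterized with a Gaussian cross-section, a synthetic stand-in
#' for labeled actin networks. Deterministic given `seed`.
#'
#' @param seed RNG seed
#' @param n_filaments number of filaments, >= 1
#' @param width full width (2 sigma of the Gaussian cross-section) [nm]
#' @param dx_f fine pixel size [nm]
#' @param n grid size [pixels]
#' @return a `scene`; `meta$skeletons` holds the sampled center lines and
#'   `meta$arc_length` their total length [nm]
#' @export
filament_scene <- function(seed = 1, n_filaments = 3, width = 100,
                           dx_f = 5, n = 208) {
  stopifnot(n_filaments >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  extent <- (n - 1) * dx_f
  d <- matrix(0, n, n)
  skels <- list()
  total_len <- 0
  for (f in seq_len(n_filaments)) {
    nw <- 4L
    wx <- stats::runif(nw, 0.1 * extent, 0.9 * extent)
    wy <- stats::runif(nw, 0.1 * extent, 0.9 * extent)
    tt <- seq(0, 1, length.out = nw)
    ts <- seq(0, 1, length.out = 40L * nw)
    px <- stats::spline(tt, wx, xout = ts)$y
    py <- stats::spline(tt, wy, xout = ts)$y
    px <- pmin(pmax(px, 0), extent)
    py <- pmin(pmax(py, 0), extent)
    total_len <- total_len + sum(sqrt(diff(px)^2 + diff(py)^2))
    skels[[f]] <- cbind(x = px, y = py)
    ix <- round(px / dx_f) + 1L
    iy <- round(py / dx_f) + 1L
    for (j in seq_along(ix)) d[ix[j], iy[j]] <- d[ix[j], iy[j]] + 1
  }
  ## Gaussian cross-section via FFT smoothing (periodic; filaments kept
  ## inside 10% margins so wrap-around is negligible)
  sigma <- width / 2
  k2 <- k_radius_grid(n, dx_f)^2
  d <- Re(ifft2(fft2(d) * exp(-k2 * sigma^2 / 2)))
  d[d < 0] <- 0
  new_scene(d, dx_f, meta = list(kind = "filaments", seed = seed,
                                 skeletons = skels, arc_length = total_len,
                                 width = width))
}

#' Centroid positions of bright spots in a density map
#'
#' Measures bead centers by intensity-weighted centroids in windows around
#' local maxima; used for geometry round-trip checks.
#'
#' @param scene a `scene`
#' @param n_spots number of spots to report
#' @param window half-width of the centroid window [nm]
#' @return matrix of (x, y) positions [nm], ordered by peak intensity
#' @export
scene_centroids <- function(scene, n_spots, window = 40) {
  d <- scene$density
  dxf <- scene$dx_f
  w <- max(1L, round(window / dxf))
  found <- matrix(NA_real_, n_spots, 2L)
  tmp <- d
  for (s in seq_len(n_spots)) {
    ij <- which(tmp == max(tmp), arr.ind = TRUE)[1L, ]
    i1 <- max(1L, ij[1L] - w); i2 <- min(nrow(d), ij[1L] + w)
    j1 <- max(1L, ij[2L] - w); j2 <- min(ncol(d), ij[2L] + w)
    patch <- d[i1:i2, j1:j2]
    xs <- (i1:i2 - 1L) * dxf; ys <- (j1:j2 - 1L) * dxf
    tot <- sum(patch)
    found[s, ] <- c(sum(rowSums(patch) * xs), sum(colSums(patch) * ys)) / tot
    tmp[i1:i2, j1:j2] <- -Inf
  }
  colnames(found) <- c("x", "y")
  found
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s: %d x %d px at %.3g nm, total density %.3g\n",
              if (is.null(x$meta$kind)) "custom" else x$meta$kind,
              nrow(x$density), ncol(x$density), x$dx_f, sum(x$density)))
  invisible(x)
}
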