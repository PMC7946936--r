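## Resolution metrics: Fourier ring correlation and two-peak resolvability.

#' Fourier ring correlation between two images
#'
#' \eqn{FRC(r) = Re[\sum_{ring} F_1 F_2^*] /
#' \sqrt{\sum_{ring}|F_1|^2 \sum_{ring}|F_2|^2}} over rings of constant
#' spatial frequency, with optional Tukey apodization to suppress edge
#' artifacts.
#'
#' @param img1,img2 images (matrices) of identical square shape
#' @param dx pixel size [nm]
#' @param ring_width ring width in frequency bins (default 1)
#' @param apodize apply a Tukey (tapered cosine) window before transforming
#' @param alpha taper fraction of the Tukey window
#' @return data.frame of class `frc_curve` with `freq` [cycles/nm], `frc`,
#'   and `n` (pixels per ring); attributes `dx`, `nyquist`
#' @export
frc_curve <- function(img1, img2, dx = 1, ring_width = 1, apodize = FALSE,
                      alpha = 0.25) {
  if (!all(dim(img1) == dim(img2))) stop("images must have the same shape")
  n <- nrow(img1)
  if (ncol(img1) != n) stop("images must be square")
  if (ring_width < 1) stop("empty rings: ring_width must be >= 1 bin")
  if (apodize) {
    w <- tukey_window(n, alpha)
    W <- outer(w, w)
    img1 <- img1 * W; img2 <- img2 * W
  }
  F1 <- fft2(img1); F2 <- fft2(img2)
  i <- 0:(n - 1L)
  i[i >= n / 2] <- i[i >= n / 2] - n
  ridx <- floor(sqrt(outer(i^2, i^2, "+")) / ring_width + 0.5)
  keep <- ridx <= floor((n / 2) / ring_width)
  ridx <- as.vector(ridx[keep])
  num <- tapply(as.vector(Re(F1 * Conj(F2))[keep]), ridx, sum)
  d1 <- tapply(as.vector((Mod(F1)^2)[keep]), ridx, sum)
  d2 <- tapply(as.vector((Mod(F2)^2)[keep]), ridx, sum)
  cnt <- tapply(rep(1, length(ridx)), ridx, sum)
  frc <- as.numeric(num) / sqrt(as.numeric(d1) * as.numeric(d2))
  freq <- as.numeric(names(num)) * ring_width / (n * dx)
  out <- data.frame(freq = freq, frc = frc, n = as.numeric(cnt))
  out <- out[order(out$freq), ]
  class(out) <- c("frc_curve", "data.frame")
  attr(out, "dx") <- dx
  attr(out, "nyquist") <- 1 / (2 * dx)
  out
}

#' @keywords internal
tukey_window <- function(n, alpha = 0.25) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

#' FRC resolution estimate
#'
#' The resolution is 1/f* where f* is the first frequency at which the FRC
#' curve crosses below the criterion (default the standard 1/7), located by
#' linear interpolation between rings. When the curve never crosses, the
#' Nyquist period is returned with `no_crossing = TRUE`.
#'
#' @param curve an `frc_curve`
#' @param criterion crossing threshold in (0, 1), default 1/7
#' @return list with `resolution` [nm], `crossing_freq` [cycles/nm], and
#'   `no_crossing`
#' @export
frc_resolution <- function(curve, criterion = 1 / 7) {
  stopifnot(criterion > 0, criterion < 1)
  f <- curve$freq[curve$freq > 0]
  v <- curve$frc[curve$freq > 0]
  below <- which(v < criterion)
  if (!length(below)) {
    return(list(resolution = 1 / attr(curve, "nyquist"),
                crossing_freq = attr(curve, "nyquist"), no_crossing = TRUE))
  }
  i <- below[1L]
  if (i == 1L) {
    fc <- f[1L]
  } else {
    fc <- f[i - 1L] + (v[i - 1L] - criterion) / (v[i - 1L] - v[i]) *
      (f[i] - f[i - 1L])
  }
  list(resolution = 1 / fc, crossing_freq = fc, no_crossing = FALSE)
}

#' Single-acquisition FRC via an even/odd frame split
#'
#' Reconstructs the even-indexed and odd-indexed frames independently and
#' returns the FRC resolution of the two half-data reconstructions (the
#' standard split when only one acquisition is available).
#'
#' @param stack a `frame_stack` with >= 4 frames
#' @param psf `psf_model` at the reconstruction pixel
#' @param options [recon_options()]
#' @param apodize passed to [frc_curve()] (default TRUE: reconstructions
#'   have hard edges)
#' @return list with `resolution` [nm], `curve` (`frc_curve`), and the two
#'   half reconstructions `recon_even`, `recon_odd`
#' @export
split_stack_frc <- function(stack, psf, options = recon_options(),
                            apodize = TRUE) {
  M <- dim(stack$frames)[3L]
  if (M < 4L) stop("even/odd split FRC needs at least 4 frames")
  pick <- function(idx) {
    s <- stack
    s$frames <- stack$frames[, , idx, drop = FALSE]
    s$seeds <- stack$seeds[idx]
    s
  }
  re <- reconstruct(pick(seq(2L, M, by = 2L)), psf, options)
  ro <- reconstruct(pick(seq(1L, M, by = 2L)), psf, options)
  cv <- frc_curve(re$rho, ro$rho, dx = re$dx, apodize = apodize)
  res <- frc_resolution(cv)
  list(resolution = res$resolution, no_crossing = res$no_crossing,
       curve = cv, recon_even = re, recon_odd = ro)
}

#' Two-peak resolvability along a line profile
#'
#' Extracts a 1-D intensity profile along a line (bilinear interpolation,
#' 10x sub-pixel sampling by default), locates local maxima, and applies a
#' Rayleigh-like dip criterion to the two highest peaks: they count as
#' resolved when the minimum between them falls below
#' `dip_threshold` x the lower peak. The separation is the peak-to-peak
#' distance in nm.
#'
#' @param image image matrix (nonnegative)
#' @param dx pixel size [nm]
#' @param line either "x" / "y" (axis through the brightest pixel) or a
#'   list/vector (x1, y1, x2, y2) of line endpoints in pixel units
#' @param dip_threshold dip criterion, default 0.8
#' @param interpolation sub-pixel profile sampling factor, default 10
#' @return list with `resolved`, `separation` [nm] (NA when unresolved or
#'   fewer than two maxima), `profile` (data.frame position [nm], value),
#'   `peaks` (positions of the two highest maxima [nm])
#' @export
two_peak_separation <- function(image, dx = 1, line = "x",
                                dip_threshold = 0.8, interpolation = 10) {
  if (any(image < 0)) image <- pmax(image, 0)
  n1 <- nrow(image); n2 <- ncol(image)
  if (is.character(line)) {
    ij <- which(image == max(image), arr.ind = TRUE)[1L, ]
    if (line == "x") {
      x1 <- 1; x2 <- n1; y1 <- y2 <- ij[2L]
    } else if (line == "y") {
      y1 <- 1; y2 <- n2; x1 <- x2 <- ij[1L]
    } else stop("line must be 'x', 'y', or endpoints (x1,y1,x2,y2)")
  } else {
    line <- as.numeric(unlist(line))
    x1 <- line[1L]; y1 <- line[2L]; x2 <- line[3L]; y2 <- line[4L]
  }
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  ns <- max(2L, ceiling(len * interpolation))
  tt <- seq(0, 1, length.out = ns)
  xs <- x1 + tt * (x2 - x1)
  ys <- y1 + tt * (y2 - y1)
  val <- bilinear_sample(image, xs, ys)
  pos <- tt * len * dx
  ## local maxima on the sampled profile; plateaus (flat tops from peaks
  ## centered between pixels) are merged to their midpoint
  v <- val
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  ## discard numerical-noise maxima in the near-zero tails
  cand <- cand[v[cand] > 1e-3 * max(v)]
  isframe_max <- integer(0)
  if (length(cand)) {
    ## candidates joined by an (almost) flat section are one plateau peak
    grp <- integer(length(cand)); grp[1L] <- 1L
    if (length(cand) > 1L) for (k in 2:length(cand)) {
      seg <- v[cand[k - 1L]:cand[k]]
      flat <- min(seg) >= (1 - 1e-9) * min(v[cand[k - 1L]], v[cand[k]])
      grp[k] <- if (flat) grp[k - 1L] else grp[k - 1L] + 1L
    }
    isframe_max <- as.integer(round(tapply(cand, grp, mean)))
  }
  out_profile <- data.frame(position = pos, value = val)
  if (length(isframe_max) < 2L)
    return(list(resolved = FALSE, separation = NA_real_,
                profile = out_profile, peaks = NA_real_))
  ord <- isframe_max[order(v[isframe_max], decreasing = TRUE)]
  p1 <- min(ord[1:2]); p2 <- max(ord[1:2])
  dip <- min(v[p1:p2])
  lower_peak <- min(v[p1], v[p2])
  resolved <- dip < dip_threshold * lower_peak
  list(resolved = resolved,
       separation = if (resolved) abs(pos[p2] - pos[p1]) else NA_real_,
       dip_ratio = dip / lower_peak,
       profile = out_profile,
       peaks = c(pos[p1], pos[p2]))
}

#' Two-peak measurement between detected 2-D peaks
#'
#' Locates the brightest local maximum of the image near each of two
#' expected positions (sub-pixel refinement by 3x3 intensity centroid),
#' then applies the dip criterion of [two_peak_separation()] along the
#' line through the two detected peaks - the cross-section-along-the-arrow
#' measurement used for bead pairs. The separation is the Euclidean
#' distance between the refined peaks.
#'
#' @param image image matrix
#' @param dx pixel size [nm]
#' @param centers two-row matrix of expected peak positions [pixels]
#' @param search_radius search radius around each expected position
#'   [pixels]
#' @param dip_threshold dip criterion, default 0.8
#' @return list with `resolved`, `separation` [nm], `peaks` (2 x 2 matrix,
#'   pixels), `dip_ratio`
#' @export
two_peak_separation_2d <- function(image, dx = 1, centers,
                                   search_radius = 3, dip_threshold = 0.8) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 2L, ncol(centers) == 2L)
  ## all interior local maxima within the union of the two search windows,
  ## strongest two kept (windows may overlap for close pairs)
  cand <- local_maxima_near(image, centers, search_radius)
  if (nrow(cand) < 2L)
    return(list(resolved = FALSE, separation = NA_real_,
                peaks = matrix(NA_real_, 2L, 2L), dip_ratio = NA_real_))
  cand <- cand[order(cand[, 3L], decreasing = TRUE), , drop = FALSE]
  pk <- rbind(refine_peak(image, cand[1L, 1:2]),
              refine_peak(image, cand[2L, 1:2]))
  if (sqrt(sum((pk[1L, ] - pk[2L, ])^2)) < 1)
    return(list(resolved = FALSE, separation = NA_real_, peaks = pk,
                dip_ratio = NA_real_))
  ## dip along the segment between the two peaks
  ns <- max(2L, ceiling(10 * sqrt(sum((pk[2L, ] - pk[1L, ])^2))))
  tt <- seq(0, 1, length.out = ns)
  prof <- bilinear_sample(image, pk[1L, 1L] + tt * (pk[2L, 1L] - pk[1L, 1L]),
                          pk[1L, 2L] + tt * (pk[2L, 2L] - pk[1L, 2L]))
  dip <- min(prof)
  lower <- min(prof[1L], prof[ns])
  resolved <- is.finite(lower) && lower > 0 && dip < dip_threshold * lower
  list(resolved = resolved,
       separation = if (resolved)
         sqrt(sum((pk[2L, ] - pk[1L, ])^2)) * dx else NA_real_,
       peaks = pk, dip_ratio = dip / lower)
}

## interior local maxima (8-neighborhood, value > 0) within `radius` of any
## of the given centers; returns a matrix of (i, j, value)
#' @keywords internal
local_maxima_near <- function(image, centers, radius) {
  n1 <- nrow(image); n2 <- ncol(image)
  out <- NULL
  i1 <- max(2L, floor(min(centers[, 1L]) - radius))
  i2 <- min(n1 - 1L, ceiling(max(centers[, 1L]) + radius))
  j1 <- max(2L, floor(min(centers[, 2L]) - radius))
  j2 <- min(n2 - 1L, ceiling(max(centers[, 2L]) + radius))
  if (i1 > i2 || j1 > j2) return(matrix(0, 0L, 3L))
  for (i in i1:i2) for (j in j1:j2) {
    if (min((i - centers[, 1L])^2 + (j - centers[, 2L])^2) > radius^2)
      next
    v <- image[i, j]
    if (v > 0 && v >= max(image[(i - 1L):(i + 1L), (j - 1L):(j + 1L)])) {
      ## suppress plateau duplicates: keep the first of equal neighbors
      if (!is.null(out) &&
          any(abs(out[, 1L] - i) <= 1 & abs(out[, 2L] - j) <= 1 &
                out[, 3L] == v)) next
      out <- rbind(out, c(i, j, v))
    }
  }
  if (is.null(out)) matrix(0, 0L, 3L) else out
}

## sub-pixel refinement by the 3x3 intensity centroid
#' @keywords internal
refine_peak <- function(image, ij) {
  i <- ij[1L]; j <- ij[2L]
  w <- image[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
  w <- w - min(w)
  if (sum(w) > 0) {
    i <- i + sum(w * matrix(-1:1, 3, 3)) / sum(w)
    j <- j + sum(w * matrix(-1:1, 3, 3, byrow = TRUE)) / sum(w)
  }
  c(i, j)
}

## brightest local maximum within a radius of one position (refined); used
## for multi-spot checks
#' @keywords internal
peak_near <- function(image, center, radius) {
  cand <- local_maxima_near(image, rbind(center), radius)
  if (nrow(cand) == 0L) return(c(NA_real_, NA_real_))
  refine_peak(image, cand[which.max(cand[, 3L]), 1:2])
}

#' @keywords internal
bilinear_sample <- function(image, xs, ys) {
  n1 <- nrow(image); n2 <- ncol(image)
  xs <- pmin(pmax(xs, 1), n1)
  ys <- pmin(pmax(ys, 1), n2)
  x0 <- pmin(floor(xs), n1 - 1L); y0 <- pmin(floor(ys), n2 - 1L)
  fx <- xs - x0; fy <- ys - y0
  image[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    image[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    image[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    image[cbind(x0 + 1L, y0 + 1L)] * fx * fy
}
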