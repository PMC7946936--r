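## Widefield fluorescence forward model:
##   frame = bin( PSF (*) (density * illumination) ), Poisson + read noise.
## All convolutions use reflective boundary padding.

#' Widefield detection PSF
#'
#' Intensity point spread function of the detection optics on a given grid.
#' `airy`: \eqn{(2 J_1(v)/v)^2}, \eqn{v = 2\pi NA r/\lambda_{em}}, truncated
#' at `radius` pixels and normalized to sum 1. `gaussian`: isotropic
#' Gaussian with \eqn{\sigma = 0.21 \lambda_{em}/NA}.
#'
#' @param na_det detection numerical aperture, > 0
#' @param lambda_em emission wavelength [nm]
#' @param dx kernel grid pixel size [nm]; must satisfy Nyquist for the OTF,
#'   dx < lambda_em / (4 NA)
#' @param radius kernel half-width [pixels]; default covers 2.5 Airy radii
#' @param model "airy" or "gaussian"
#' @return object of class `psf_model`: `kernel` ((2r+1) square, sums to 1),
#'   `dx`, `na_det`, `lambda_em`, `model`
#' @export
widefield_psf <- function(na_det, lambda_em, dx, radius = NULL,
                          model = c("airy", "gaussian")) {
  model <- match.arg(model)
  stopifnot(na_det > 0, lambda_em > 0, dx > 0)
  if (dx >= lambda_em / (4 * na_det))
    stop("dx = ", dx, " nm undersamples the PSF: need dx < lambda_em/(4 NA) = ",
         round(lambda_em / (4 * na_det), 2), " nm")
  if (is.null(radius))
    radius <- ceiling(2.5 * 0.61 * lambda_em / na_det / dx)
  r <- dx * sqrt(outer((-radius:radius)^2, (-radius:radius)^2, "+"))
  if (model == "airy") {
    v <- 2 * pi * na_det * r / lambda_em
    k <- matrix(1, nrow(r), ncol(r))
    nz <- v > 0
    k[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
  } else {
    sigma <- 0.21 * lambda_em / na_det
    k <- exp(-r^2 / (2 * sigma^2))
  }
  structure(list(kernel = k / sum(k), dx = dx, na_det = na_det,
                 lambda_em = lambda_em, model = model, radius = radius),
            class = "psf_model")
}

## Precompute a reflective-boundary convolver for images of size n1 x n2.
## Returns function(x) performing PSF convolution via padded FFT.
#' @keywords internal
make_convolver <- function(n1, n2, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kmax <- min(n1, n2) - 1L
  if (kr > kmax) {   # trim an oversized kernel to the image size
    keep <- (kr - kmax + 1L):(kr + kmax + 1L)
    kernel <- kernel[keep, keep]
    kernel <- kernel / sum(kernel)
    kr <- kmax
  }
  p <- kr
  m1 <- n1 + 2L * p; m2 <- n2 + 2L * p
  kbig <- matrix(0, m1, m2)
  ## center kernel at (1,1) with wrap
  idx1 <- ((-kr:kr) %% m1) + 1L
  idx2 <- ((-kr:kr) %% m2) + 1L
  kbig[idx1, idx2] <- kernel[]
  otf <- fft2(kbig)
  function(x) {
    xp <- pad_reflect(x, p)
    out <- Re(ifft2(fft2(xp) * otf))
    crop_center(out, p)
  }
}

#' @keywords internal
bin_image <- function(x, b) {
  if (b == 1L) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  if (n1 %% b != 0L || n2 %% b != 0L)
    stop("image size not divisible by the binning factor")
  ## sum over b x b blocks
  x1 <- rowsum(x, rep(seq_len(n1 %/% b), each = b))
  t(rowsum(t(x1), rep(seq_len(n2 %/% b), each = b)))
}

#' Simulate one camera frame
#'
#' Applies the forward model: fluorophore density times illumination,
#' blurred by the detection PSF (reflective boundaries), binned to camera
#' pixels, scaled to expected photons, then Poisson shot noise plus Gaussian
#' read noise. Deterministic given `seed`; `noiseless = TRUE` returns the
#' expected image.
#'
#' @param scene a `scene` (fine grid)
#' @param pattern a `speckle_pattern` on the same grid (or a plain matrix of
#'   illumination intensity); use `NULL` for uniform illumination
#' @param psf a `psf_model` with `dx` equal to the scene's fine pixel
#' @param binning camera pixel = `binning` fine pixels (integer >= 1)
#' @param photons_scale expected photons per unit density per frame at unit
#'   illumination (default 5000, i.e. photons per bead per frame)
#' @param background expected background photons per camera pixel
#' @param read_sd Gaussian read noise standard deviation [counts]
#' @param seed RNG seed for the noise
#' @param noiseless return the noise-free expectation
#' @return camera image matrix [counts]
#' @export
acquire_frame <- function(scene, pattern, psf, binning = 1L,
                          photons_scale = 5000, background = 0,
                          read_sd = 0, seed = NULL, noiseless = FALSE) {
  I <- illum_matrix(pattern, scene)
  conv <- make_convolver(nrow(scene$density), ncol(scene$density),
                         psf$kernel)
  expected <- photons_scale * bin_image(conv(scene$density * I), binning) +
    background
  if (noiseless) return(expected)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  n <- length(expected)
  frame <- matrix(stats::rpois(n, pmax(expected, 0)), nrow(expected)) +
    matrix(stats::rnorm(n, 0, read_sd), nrow(expected))
  frame
}

#' @keywords internal
illum_matrix <- function(pattern, scene) {
  if (is.null(pattern)) return(matrix(1, nrow(scene$density),
                                      ncol(scene$density)))
  I <- if (inherits(pattern, "speckle_pattern")) pattern$intensity else
    pattern
  if (!identical(dim(I), dim(scene$density)))
    stop("illumination grid (", paste(dim(I), collapse = "x"),
         ") does not match the scene grid (",
         paste(dim(scene$density), collapse = "x"), ")")
  I
}

#' Simulate a multi-frame stack
#'
#' One camera frame per illumination pattern. Frame noise seeds default to
#' `noise_seed + 0:(M-1)`; all seeds and per-pattern metadata are recorded
#' on the stack.
#'
#' @inheritParams acquire_frame
#' @param patterns list of illumination patterns (`speckle_pattern`s or
#'   matrices), length >= 1
#' @param noise_seed base seed for the per-frame noise
#' @return object of class `frame_stack`: `frames` (n x n x M array),
#'   `dx_c` camera pixel [nm], `noise` descriptor, `seeds`, `meta`
#' @export
acquire_stack <- function(scene, patterns, psf, binning = 1L,
                          photons_scale = 5000, background = 0,
                          read_sd = 0, noise_seed = 1L) {
  if (length(patterns) < 1L) stop("at least one illumination pattern needed")
  conv <- make_convolver(nrow(scene$density), ncol(scene$density),
                         psf$kernel)
  M <- length(patterns)
  seeds <- noise_seed + 0:(M - 1L)
  first <- TRUE
  frames <- NULL
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (m in seq_len(M)) {
    I <- illum_matrix(patterns[[m]], scene)
    expected <- photons_scale * bin_image(conv(scene$density * I), binning) +
      background
    set.seed(seeds[m])
    fr <- matrix(stats::rpois(length(expected), pmax(expected, 0)),
                 nrow(expected)) +
      matrix(stats::rnorm(length(expected), 0, read_sd), nrow(expected))
    if (first) {
      frames <- array(0, c(nrow(fr), ncol(fr), M))
      first <- FALSE
    }
    frames[, , m] <- fr
  }
  pat_meta <- lapply(patterns, function(p)
    if (inherits(p, "speckle_pattern")) p$meta else list())
  structure(list(frames = frames, dx_c = scene$dx_f * binning,
                 noise = list(photons_scale = photons_scale,
                              background = background, read_sd = read_sd),
                 seeds = seeds,
                 meta = list(dx_f = scene$dx_f, binning = binning,
                             patterns = pat_meta)),
            class = "frame_stack")
}

#' Diffraction-limited image of a stack
#'
#' Pixelwise mean over all frames: under illumination patterns that sum to a
#' uniform field this is the widefield image of the object.
#'
#' @param stack a `frame_stack`
#' @return image matrix
#' @export
diffraction_limited <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"), dim(stack$frames)[3L] >= 1L)
  apply(stack$frames, c(1L, 2L), mean)
}

#' Per-frame intensity normalization
#'
#' Divides every frame by its own mean, the standard preprocessing applied
#' to speckle stacks before blind-SIM reconstruction.
#'
#' @param stack a `frame_stack`
#' @return the normalized `frame_stack`
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  M <- dim(stack$frames)[3L]
  for (m in seq_len(M)) {
    mu <- mean(stack$frames[, , m])
    if (mu <= 0) stop("frame ", m, " has non-positive mean")
    stack$frames[, , m] <- stack$frames[, , m] / mu
  }
  stack$meta$normalized <- TRUE
  stack
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, camera pixel %.3g nm\n",
    d[3L], d[1L], d[2L], x$dx_c))
  cat(sprintf("  photons_scale = %g, background = %g, read_sd = %g%s\n",
              x$noise$photons_scale, x$noise$background, x$noise$read_sd,
              if (isTRUE(x$meta$normalized)) " (normalized)" else ""))
  invisible(x)
}
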