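## Shared FFT helpers. Conventions used throughout the package:
##  - angular spatial frequencies k [rad/nm]; k0 = 2*pi/lambda
##  - fft2()/ifft2() form an exact inverse pair (1/N normalization on inverse)
##  - grids are square with pixel size dx [nm]

#' Angular FFT frequency axis
#'
#' DFT frequencies in rad/nm for an n-point axis with pixel size dx,
#' in standard FFT order (0, positive, negative).
#'
#' @param n number of samples
#' @param dx sample spacing [nm]
#' @return numeric vector of length n, angular frequencies [rad/nm]
#' @keywords internal
fft_freq <- function(n, dx) {
  i <- 0:(n - 1L)
  i[i >= n / 2] <- i[i >= n / 2] - n
  2 * pi * i / (n * dx)
}

#' @keywords internal
fft2 <- function(x) stats::fft(x)

#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## 2-D FFT applied slice-by-slice to a 3-D array (n1 x n2 x m), batched
## through mvfft so the per-slice R overhead is paid once.
#' @keywords internal
fft2_stack <- function(a, inverse = FALSE) {
  d <- dim(a)
  m <- stats::mvfft(matrix(a, d[1L], d[2L] * d[3L]), inverse = inverse)
  a2 <- aperm(array(m, d), c(2L, 1L, 3L))
  m2 <- stats::mvfft(matrix(a2, d[2L], d[1L] * d[3L]), inverse = inverse)
  out <- aperm(array(m2, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  if (inverse) out / (d[1L] * d[2L]) else out
}

## Radial |k| map [rad/nm] for an n x n grid with pixel size dx.
#' @keywords internal
k_radius_grid <- function(n, dx) {
  k <- fft_freq(n, dx)
  sqrt(outer(k^2, k^2, "+"))
}

#' Radially averaged profile of a 2-D map in FFT layout
#'
#' Averages map values over rings of |k| (or radius r for real-space maps).
#' Ring width is one frequency (or pixel) bin.
#'
#' @param map real matrix in FFT index layout (DC at [1,1]) or plain layout
#'   when `radius` is supplied
#' @param radius matrix of the same shape giving the radius of each cell
#' @param bin_width ring width in the units of `radius`
#' @return data.frame with columns `radius` (ring center) and `mean`
#' @keywords internal
radial_average <- function(map, radius, bin_width) {
  idx <- floor(radius / bin_width + 0.5)
  s <- tapply(as.vector(map), as.vector(idx), mean)
  r <- as.numeric(names(s)) * bin_width
  data.frame(radius = r, mean = as.numeric(s))
}

## Reflective (symmetric) padding of a matrix by p pixels on every side.
#' @keywords internal
pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  if (p > n1 || p > n2) stop("padding exceeds image size")
  ri <- c(p:1, 1:n1, n1:(n1 - p + 1L))
  ci <- c(p:1, 1:n2, n2:(n2 - p + 1L))
  x[ri, ci, drop = FALSE]
}

#' @keywords internal
crop_center <- function(x, p) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[(p + 1L):(n1 - p), (p + 1L):(n2 - p), drop = FALSE]
}
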