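#' Generate a Gaussian-correlated random rough surface
#'
#' Spectral synthesis of a zero-mean random height map with Gaussian
#' autocorrelation \eqn{\exp(-r^2/C_l^2)}: white Gaussian noise is filtered
#' in the Fourier domain by the amplitude filter
#' \eqn{\exp(-k^2 C_l^2/8)} (so the power spectrum is
#' \eqn{\exp(-k^2 C_l^2/4)}, the transform of the target autocorrelation),
#' then mean-subtracted and rescaled to the exact target RMS. The synthesis
#' is periodic (wrap-around correlation at the map edges). Deterministic
#' given `seed`.
#'
#' @param n grid size in pixels (square map), >= 32
#' @param dx pixel size [nm]
#' @param rms target root-mean-square height [nm] (enforced exactly)
#' @param corr_length target 1/e correlation length \eqn{C_l} [nm]; must
#'   exceed 2*dx (sampling)
#' @param seed integer RNG seed
#' @return object of class `height_map`: list with `heights` (n x n matrix,
#'   nm), `dx`, `rms`, `corr_length`, `seed`
#' @examples
#' hm <- generate_height_map(128, 5.86, rms = 1.1, corr_length = 35, seed = 1)
#' surface_statistics(hm)
#' @export
generate_height_map <- function(n, dx, rms, corr_length, seed) {
  stopifnot(n >= 32, dx > 0, rms >= 0)
  if (corr_length <= 2 * dx)
    stop("corr_length must exceed 2*dx: the surface would be undersampled")
  h <- matrix(0, n, n)
  if (rms > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    noise <- matrix(stats::rnorm(n * n), n, n)
    k2 <- k_radius_grid(n, dx)^2
    filt <- exp(-k2 * corr_length^2 / 8)
    h <- Re(ifft2(fft2(noise) * filt))
    h <- h - mean(h)
    s <- stats::sd(as.vector(h)) * sqrt((n * n - 1) / (n * n))
    h <- h * (rms / s)
  }
  structure(list(heights = h, dx = dx, rms = rms,
                 corr_length = corr_length, seed = seed),
            class = "height_map")
}

#' Measured statistics of a height map
#'
#' RMS is the population standard deviation of the heights. The correlation
#' length is the radius at which the radially averaged normalized (circular)
#' autocorrelation first falls below 1/e, located by linear interpolation
#' between radial bins. For a flat map the correlation length is undefined
#' and returned as NA.
#'
#' @param map a `height_map` (or plain matrix plus `dx`)
#' @param dx pixel size [nm] when `map` is a plain matrix
#' @return list with `rms` [nm] and `corr_length` [nm]
#' @export
surface_statistics <- function(map, dx = NULL) {
  if (inherits(map, "height_map")) {
    h <- map$heights; dx <- map$dx
  } else {
    h <- map
    if (is.null(dx)) stop("dx required for a plain matrix")
  }
  stopifnot(length(h) > 0)
  n <- nrow(h)
  h0 <- h - mean(h)
  rms <- sqrt(mean(h0^2))
  if (rms == 0) return(list(rms = 0, corr_length = NA_real_))
  ## circular autocorrelation via Wiener-Khinchin
  ac <- Re(ifft2(Mod(fft2(h0))^2)) / (n * n * rms^2)
  i <- 0:(n - 1L)
  i[i >= n / 2] <- i[i >= n / 2] - n
  r <- sqrt(outer(i^2, i^2, "+")) * dx
  prof <- radial_average(ac, r, dx)
  prof <- prof[order(prof$radius), ]
  below <- which(prof$mean < exp(-1))
  if (!length(below)) return(list(rms = rms, corr_length = NA_real_))
  i <- below[1L]
  if (i == 1L) return(list(rms = rms, corr_length = prof$radius[1L]))
  ## linear interpolation between the straddling bins
  r1 <- prof$radius[i - 1L]; r2 <- prof$radius[i]
  a1 <- prof$mean[i - 1L]; a2 <- prof$mean[i]
  cl <- r1 + (a1 - exp(-1)) / (a1 - a2) * (r2 - r1)
  list(rms = rms, corr_length = cl)
}

#' @export
print.height_map <- function(x, ...) {
  st <- surface_statistics(x)
  cat(sprintf(
    "<height_map> %d x %d px, dx = %.3g nm; RMS = %.3g nm, C_l = %.3g nm\n",
    nrow(x$heights), ncol(x$heights), x$dx, st$rms, st$corr_length))
  invisible(x)
}
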