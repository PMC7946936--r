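## Speckle synthesis above the HMM.
##
## The full-wave scattering problem is modeled by a first-Born,
## single-scattering angular-spectrum surrogate: the incident diffraction-
## limited field is multiplied by a linearized thin phase screen
## (1 + i*beta*h(r)) representing interface roughness, the scattered part of
## the resulting angular spectrum is filtered by the multilayer transfer
## amplitude (transfer-matrix t for propagating components, Bloch-band
## attenuation exp(-Im(K)*L) for evanescent ones) and the coherent specular
## components are tracked analytically (off-grid wavevectors, no DFT
## leakage). Scalar field, TM transfer function.

#' Random diffraction-limited incident field
#'
#' A set of plane waves with wavevectors drawn uniformly over the incidence
#' NA disk and independent uniform phases, modeling the scrambled multimode-
#' fiber illumination. Deterministic given `seed`.
#'
#' @param wavelength vacuum wavelength [nm]
#' @param na_inc incidence numerical aperture in [0, 1)
#' @param n_modes number of plane-wave components, >= 1
#' @param seed integer RNG seed
#' @return object of class `plane_wave_set`: `kx`, `ky` [rad/nm], complex
#'   `amplitude`, plus `wavelength`, `na_inc`, `seed`
#' @export
incident_field <- function(wavelength, na_inc = 0.2, n_modes = 100, seed = 1) {
  stopifnot(na_inc >= 0, na_inc < 1, n_modes >= 1)
  k0 <- 2 * pi / wavelength
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  kr <- na_inc * k0 * sqrt(stats::runif(n_modes))
  az <- stats::runif(n_modes, 0, 2 * pi)
  ph <- stats::runif(n_modes, 0, 2 * pi)
  structure(list(kx = kr * cos(az), ky = kr * sin(az),
                 amplitude = exp(1i * ph),
                 wavelength = wavelength, na_inc = na_inc, seed = seed),
            class = "plane_wave_set")
}

#' Single oblique plane wave
#'
#' One unit-amplitude plane wave at polar incidence angle `theta_deg` in the
#' x-z plane, used for the angle-tunability and decorrelation analyses.
#'
#' @param wavelength vacuum wavelength [nm]
#' @param theta_deg polar incidence angle [degrees]
#' @return a `plane_wave_set` with a single component
#' @export
plane_wave <- function(wavelength, theta_deg = 0) {
  k0 <- 2 * pi / wavelength
  structure(list(kx = k0 * sin(theta_deg * pi / 180), ky = 0,
                 amplitude = 1 + 0i,
                 wavelength = wavelength, na_inc = 0, seed = NA_integer_),
            class = "plane_wave_set")
}

## Incident complex field on the grid: sum of exact (off-grid) phase ramps,
## assembled as a rank-m complex matrix product.
#' @keywords internal
incident_field_map <- function(incident, n, dx) {
  x <- (0:(n - 1L)) * dx
  X <- exp(1i * outer(x, incident$kx)) *
    matrix(incident$amplitude, n, length(incident$kx), byrow = TRUE)
  Y <- exp(1i * outer(incident$ky, x))
  X %*% Y
}

#' Multilayer transfer amplitude versus in-plane wavevector
#'
#' Transfer amplitude t(|k|) of the HMM for the speckle model: the exact TM
#' transfer-matrix transmission amplitude of the stack, evaluated for
#' propagating and evanescent in-plane wavevectors alike (no power
#' normalization is involved for the evanescent part, so the amplitude is
#' well defined at every k). Beyond the Bloch band of the multilayer this
#' amplitude decays with the per-period Bloch attenuation, so components
#' past [max_k_support()] are automatically suppressed; within high-k Bloch
#' bands and at the surface-plasmon resonances of the stack it is resonantly
#' enhanced. Returned as an interpolating function of |k| built from a fine
#' radial profile.
#'
#' @param stack a `layer_stack`
#' @param wavelength vacuum wavelength [nm]
#' @param k_max largest |k| the filter will be evaluated at [rad/nm]
#' @param n_samples radial profile resolution
#' @return a function t(k) vectorized over |k| (class `transfer_filter`)
#' @export
transmission_filter <- function(stack, wavelength, k_max,
                                n_samples = 4096L) {
  kprof <- seq(0, k_max * 1.0001 + 1e-9, length.out = n_samples)
  tprof <- vapply(kprof, function(kp)
    Mod(tmm_amplitude(stack, wavelength, kp, "TM")), 0)
  tprof[!is.finite(tprof)] <- 0
  f <- stats::approxfun(kprof, tprof, rule = 2)
  structure(function(k) f(abs(k)), class = "transfer_filter")
}

#' Angular spectrum transmitted through the rough HMM
#'
#' First-Born single-scattering surrogate: each incident plane-wave
#' component q contributes a specular term \eqn{t(q) a_q} at wavevector q
#' plus a scattered halo \eqn{i\beta a_q \tilde h(k - q)} filtered by the
#' transfer amplitude t(k), all components summed coherently. The scattered
#' halo lives on the DFT grid of the roughness map; specular components keep
#' their exact off-grid wavevectors and are stored separately (added back
#' analytically on propagation), which avoids DFT leakage of the strong
#' coherent background.
#'
#' @param incident a `plane_wave_set`
#' @param stack a `layer_stack`
#' @param roughness a `height_map` defining the spatial grid; its RMS sets
#'   the scattered power
#' @param wavelength vacuum wavelength [nm]
#' @param beta roughness coupling constant [1/nm]; the default
#'   sqrt(0.2)/1.1 puts ~20% of the specular power into the scattered halo
#'   at the 1.1 nm reference roughness (before spectral filtering)
#' @param filter optional precomputed [transmission_filter()] (avoids
#'   recomputing the radial transfer profile in repeated calls)
#' @return object of class `angular_spectrum`: complex matrix `a` in
#'   amplitude units (field(r) = sum_k a_k exp(ikr)) holding the scattered
#'   halo, a `specular` data.frame (kx, ky, amplitude), `dx`, `wavelength`
#' @export
hmm_transmitted_spectrum <- function(incident, stack, roughness, wavelength,
                                     beta = sqrt(0.2) / 1.1, filter = NULL) {
  stopifnot(inherits(incident, "plane_wave_set"),
            inherits(roughness, "height_map"))
  h <- roughness$heights
  n <- nrow(h)
  if (ncol(h) != n) stop("roughness grid must be square")
  dx <- roughness$dx
  kr <- k_radius_grid(n, dx)
  if (is.null(filter))
    filter <- transmission_filter(stack, wavelength,
                                  max(max(kr), max(sqrt(incident$kx^2 +
                                                          incident$ky^2))))
  e_inc <- incident_field_map(incident, n, dx)
  a <- fft2(1i * beta * h * e_inc) / (n * n) * filter(kr)
  specular <- data.frame(
    kx = incident$kx, ky = incident$ky,
    amplitude = incident$amplitude *
      filter(sqrt(incident$kx^2 + incident$ky^2)))
  structure(list(a = a, specular = specular, dx = dx,
                 wavelength = wavelength),
            class = "angular_spectrum")
}

#' Propagate an angular spectrum to a height above the surface
#'
#' Each component is advanced by \eqn{\exp(i k_z z)} with
#' \eqn{k_z = \sqrt{k_0^2 - |k|^2}} (principal branch): propagating
#' components accumulate phase, evanescent ones decay as
#' \eqn{\exp(-|k_z| z)}. Grid components go through the inverse DFT;
#' specular components are added as exact plane waves.
#'
#' @param spectrum an `angular_spectrum`
#' @param z height above the top surface [nm], >= 0
#' @return object of class `field_map`: complex matrix `field`, `dx`,
#'   `wavelength`, `z`
#' @export
field_above_surface <- function(spectrum, z = 10) {
  stopifnot(inherits(spectrum, "angular_spectrum"), z >= 0)
  n <- nrow(spectrum$a)
  dx <- spectrum$dx
  k0 <- 2 * pi / spectrum$wavelength
  kr <- k_radius_grid(n, dx)
  kz <- sqrt(as.complex(k0^2 - kr^2))
  kz <- ifelse(Im(kz) < 0, -kz, kz)
  field <- stats::fft(spectrum$a * exp(1i * kz * z), inverse = TRUE)
  sp <- spectrum$specular
  if (nrow(sp) > 0) {
    kzs <- sqrt(as.complex(k0^2 - sp$kx^2 - sp$ky^2))
    kzs <- ifelse(Im(kzs) < 0, -kzs, kzs)
    pw <- list(kx = sp$kx, ky = sp$ky,
               amplitude = sp$amplitude * exp(1i * kzs * z),
               wavelength = spectrum$wavelength)
    class(pw) <- "plane_wave_set"
    field <- field + incident_field_map(pw, n, dx)
  }
  structure(list(field = field, dx = dx,
                 wavelength = spectrum$wavelength, z = z),
            class = "field_map")
}

#' Speckle intensity pattern
#'
#' |E|^2 of a field map, normalized to unit mean.
#'
#' @param field a `field_map`
#' @param meta optional list of provenance metadata stored on the pattern
#' @return object of class `speckle_pattern`: nonnegative matrix `intensity`
#'   with unit mean, `dx`, `wavelength`, `z`, `meta`
#' @export
speckle_intensity <- function(field, meta = list()) {
  stopifnot(inherits(field, "field_map"))
  I <- Mod(field$field)^2
  m <- mean(I)
  if (m == 0) stop("degenerate field: all-zero intensity")
  structure(list(intensity = I / m, dx = field$dx,
                 wavelength = field$wavelength, z = field$z, meta = meta),
            class = "speckle_pattern")
}

#' One-call speckle pattern above the rough HMM
#'
#' Convenience pipeline: incident field -> transmitted spectrum ->
#' propagation to height z -> normalized intensity.
#'
#' @inheritParams hmm_transmitted_spectrum
#' @param z observation height above the top surface [nm] (default 10)
#' @return a `speckle_pattern`
#' @export
hmm_speckle <- function(incident, stack, roughness, wavelength = NULL,
                        z = 10, beta = sqrt(0.2) / 1.1, filter = NULL) {
  if (is.null(wavelength)) wavelength <- incident$wavelength
  sp <- hmm_transmitted_spectrum(incident, stack, roughness, wavelength,
                                 beta = beta, filter = filter)
  fl <- field_above_surface(sp, z)
  speckle_intensity(fl, meta = list(seed = incident$seed,
                                    na_inc = incident$na_inc))
}

#' Free-space (diffraction-limited) speckle control
#'
#' The intensity of the incident plane-wave composite itself, propagated a
#' height z in free space with no HMM and no roughness: the
#' diffraction-limited control whose intensity spectrum is bounded by
#' 2 NA_inc k0.
#'
#' @param incident a `plane_wave_set`
#' @param n,dx output grid (pixels, nm)
#' @param z propagation distance [nm]
#' @return a `speckle_pattern`
#' @export
free_space_speckle <- function(incident, n, dx, z = 0) {
  k0 <- 2 * pi / incident$wavelength
  kzs <- sqrt(as.complex(k0^2 - incident$kx^2 - incident$ky^2))
  kzs <- ifelse(Im(kzs) < 0, -kzs, kzs)
  pw <- incident
  pw$amplitude <- incident$amplitude * exp(1i * kzs * z)
  field <- structure(list(field = incident_field_map(pw, n, dx), dx = dx,
                          wavelength = incident$wavelength, z = z),
                     class = "field_map")
  speckle_intensity(field, meta = list(seed = incident$seed,
                                       na_inc = incident$na_inc,
                                       free_space = TRUE))
}

#' Radially averaged magnitude transfer function of a speckle pattern
#'
#' Magnitude of the discrete spectrum of the mean-subtracted intensity,
#' averaged over rings of one frequency bin and normalized to 1 at the
#' lowest nonzero frequency.
#'
#' @param pattern a `speckle_pattern` (square grid)
#' @param apodize apply a Hann window before the transform; suppresses the
#'   spectral leakage of off-grid tones (recommended when comparing
#'   spectral support between patterns)
#' @return data.frame with `freq` [cycles/nm] and `mtf`
#' @export
radial_mtf <- function(pattern, apodize = FALSE) {
  stopifnot(inherits(pattern, "speckle_pattern"))
  I <- pattern$intensity
  n <- nrow(I)
  if (ncol(I) != n) stop("pattern must be square")
  I <- I - mean(I)
  if (apodize) {
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    I <- I * outer(w, w)
  }
  mag <- Mod(fft2(I))
  i <- 0:(n - 1L)
  i[i >= n / 2] <- i[i >= n / 2] - n
  ridx <- sqrt(outer(i^2, i^2, "+"))
  prof <- radial_average(mag, ridx, 1)
  prof <- prof[order(prof$radius), ]
  prof <- prof[prof$radius > 0, ]
  norm <- if (prof$mean[1L] > 0) prof$mean[1L] else 1  # uniform pattern
  data.frame(freq = prof$radius / (n * pattern$dx),
             mtf = prof$mean / norm)
}

#' Zero-lag Pearson correlation of two speckle patterns
#'
#' @param p1,p2 `speckle_pattern`s on identical grids
#' @return Pearson correlation coefficient
#' @export
cross_correlation <- function(p1, p2) {
  stopifnot(inherits(p1, "speckle_pattern"), inherits(p2, "speckle_pattern"))
  if (!identical(dim(p1$intensity), dim(p2$intensity)))
    stop("patterns must share the same grid")
  v1 <- as.vector(p1$intensity); v2 <- as.vector(p2$intensity)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("undefined correlation: constant pattern")
  stats::cor(v1, v2)
}

#' Speckle decorrelation angle
#'
#' Smallest incidence-angle difference (on a 1-degree grid) at which the
#' correlation between the pattern at normal incidence and the pattern at
#' theta drops below `threshold`, averaged over roughness seeds. Returns NA
#' with a warning when the correlation never crosses the threshold within
#' the scanned range.
#'
#' @param stack a `layer_stack`
#' @param wavelength vacuum wavelength [nm]
#' @param threshold correlation threshold in (0, 1), default 0.5
#' @param angles_deg scan grid of angle differences [degrees]
#' @param seeds roughness seeds to average over
#' @param n,dx speckle grid (default 1 um x 1 um at 2 nm)
#' @param rms,corr_length roughness parameters [nm]
#' @param z observation height [nm]
#' @param beta roughness coupling [1/nm]
#' @return list with `angle` (mean crossing angle, degrees), `per_seed`
#'   vector, and `correlation` matrix (angles x seeds)
#' @export
decorrelation_angle <- function(stack, wavelength = 488, threshold = 0.5,
                                angles_deg = 0:30, seeds = 1:5,
                                n = 500, dx = 2, rms = 1.1, corr_length = 35,
                                z = 10, beta = sqrt(0.2) / 1.1) {
  stopifnot(threshold > 0, threshold < 1)
  k0 <- 2 * pi / wavelength
  filt <- transmission_filter(stack, wavelength,
                              max(k_radius_grid(n, dx)) + k0)
  cors <- matrix(NA_real_, length(angles_deg), length(seeds),
                 dimnames = list(angles_deg, seeds))
  per_seed <- rep(NA_real_, length(seeds))
  for (si in seq_along(seeds)) {
    rough <- generate_height_map(n, dx, rms, corr_length, seed = seeds[si])
    p0 <- hmm_speckle(plane_wave(wavelength, 0), stack, rough,
                      wavelength, z = z, beta = beta, filter = filt)
    for (ai in seq_along(angles_deg)) {
      th <- angles_deg[ai]
      if (th == 0) { cors[ai, si] <- 1; next }
      p <- hmm_speckle(plane_wave(wavelength, th), stack, rough,
                       wavelength, z = z, beta = beta, filter = filt)
      ## constant patterns (pure specular transmission) stay fully
      ## correlated: count them as correlation 1
      cors[ai, si] <- tryCatch(cross_correlation(p0, p),
                               error = function(e) 1)
      if (is.na(per_seed[si]) && cors[ai, si] < threshold)
        per_seed[si] <- th
    }
  }
  if (all(is.na(per_seed))) {
    warning("correlation never crossed the threshold in the scanned range")
    return(list(angle = NA_real_, per_seed = per_seed, correlation = cors))
  }
  list(angle = mean(per_seed, na.rm = TRUE), per_seed = per_seed,
       correlation = cors)
}

#' @export
print.speckle_pattern <- function(x, ...) {
  cat(sprintf(
    "<speckle_pattern> %d x %d px, dx = %.3g nm, lambda = %g nm, z = %g nm\n",
    nrow(x$intensity), ncol(x$intensity), x$dx, x$wavelength, x$z))
  cat(sprintf("  contrast (sd/mean) = %.3f\n", stats::sd(x$intensity)))
  invisible(x)
}
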