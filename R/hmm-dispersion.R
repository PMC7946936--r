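#' Periodic multilayer unit cell
#'
#' Two-layer unit cell of a periodic metal/dielectric multilayer, with period
#' \eqn{\Lambda = d_1 + d_2} and metal fill fraction \eqn{f = d_1/\Lambda}.
#'
#' @param material_1,material_2 `optical_material`s of the two layers
#' @param d_1,d_2 layer thicknesses [nm], both > 0
#' @return object of class `unit_cell`
#' @examples
#' unit_cell(ag_material(), 10, silica_material(), 10)  # 20 nm period
#' @export
unit_cell <- function(material_1, d_1, material_2, d_2) {
  stopifnot(d_1 > 0, d_2 > 0)
  structure(list(material_1 = material_1, d_1 = d_1,
                 material_2 = material_2, d_2 = d_2,
                 period = d_1 + d_2, fill = d_1 / (d_1 + d_2)),
            class = "unit_cell")
}

#' Effective-medium permittivities of a metal/dielectric multilayer
#'
#' First-order effective medium theory of a deeply subwavelength two-phase
#' multilayer: in-plane \eqn{\epsilon_\parallel = f\epsilon_m +
#' (1-f)\epsilon_d} and out-of-plane \eqn{\epsilon_\perp =
#' \epsilon_m\epsilon_d/(f\epsilon_d + (1-f)\epsilon_m)}. Hyperbolic
#' dispersion corresponds to \eqn{Re(\epsilon_\parallel)} and
#' \eqn{Re(\epsilon_\perp)} of opposite sign.
#'
#' @param f metal fill fraction in [0, 1]
#' @param eps_m,eps_d complex permittivities of metal and dielectric
#' @return list with `eps_parallel` and `eps_perp`
#' @export
emt_permittivities <- function(f, eps_m, eps_d) {
  stopifnot(f >= 0, f <= 1)
  den <- f * eps_d + (1 - f) * eps_m
  if (Mod(den) < 1e-12 * (Mod(eps_m) + Mod(eps_d)))
    stop("singular mixture: f*eps_d + (1-f)*eps_m is (near) zero")
  list(eps_parallel = f * eps_m + (1 - f) * eps_d,
       eps_perp = eps_m * eps_d / den)
}

## Principal-branch complex arccos.
#' @keywords internal
cacos <- function(z) -1i * log(z + 1i * sqrt(1 - z^2))

#' Bloch wavevector of a periodic two-layer multilayer
#'
#' Solves the Bloch dispersion relation
#' \deqn{\cos(K\Lambda) = \cos(k_1 d_1)\cos(k_2 d_2) -
#'   \tfrac12(\eta + 1/\eta)\sin(k_1 d_1)\sin(k_2 d_2)}
#' with \eqn{k_i} the layer-normal wavevectors and, for TM polarization,
#' \eqn{\eta = \epsilon_2 k_1 / (\epsilon_1 k_2)} (TE: \eqn{\eta = k_2/k_1}).
#' The branch is chosen with \eqn{Im(K) \ge 0} and
#' \eqn{Re(K)\Lambda \in [0, \pi]}; \eqn{Im(K)\Lambda} is the per-period
#' field attenuation.
#'
#' @param cell a `unit_cell`
#' @param wavelength vacuum wavelength [nm]
#' @param k_parallel in-plane wavevector [rad/nm]; may be a vector
#' @param polarization "TM" or "TE"
#' @return complex Bloch wavevector K [rad/nm], vectorized over `k_parallel`
#' @export
bloch_kz <- function(cell, wavelength, k_parallel,
                     polarization = c("TM", "TE")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(cell, "unit_cell"))
  k0 <- 2 * pi / wavelength
  e1 <- permittivity(cell$material_1, wavelength)
  e2 <- permittivity(cell$material_2, wavelength)
  k1 <- kz_layer(e1, k0, k_parallel)
  k2 <- kz_layer(e2, k0, k_parallel)
  eta <- if (polarization == "TM") (e2 * k1) / (e1 * k2) else k2 / k1
  rhs <- cos(k1 * cell$d_1) * cos(k2 * cell$d_2) -
    0.5 * (eta + 1 / eta) * sin(k1 * cell$d_1) * sin(k2 * cell$d_2)
  K <- cacos(rhs) / cell$period
  ## enforce Im(K) >= 0, then fold Re into [0, pi/period]
  K <- ifelse(Im(K) < 0, -K, K)
  re <- Re(K) %% (2 * pi / cell$period)
  re <- ifelse(re > pi / cell$period, 2 * pi / cell$period - re, re)
  complex(real = re, imaginary = Im(K))
}

#' Isofrequency curve of air, EMT, or Bloch multilayer
#'
#' Dispersion \eqn{k_z(k_x)} at fixed wavelength, normalized to the
#' free-space wavevector \eqn{k_0 = 2\pi/\lambda}. For air
#' \eqn{k_z = \sqrt{k_0^2 - k_x^2}}; for a TM extraordinary wave in an EMT
#' slab \eqn{k_x^2/\epsilon_\perp + k_z^2/\epsilon_\parallel = k_0^2};
#' for the practical multilayer \eqn{k_z} is the Bloch wavevector.
#'
#' @param model "air", "emt" or "bloch"
#' @param kx_over_k0 grid of normalized in-plane wavevectors
#' @param wavelength vacuum wavelength [nm]
#' @param cell `unit_cell` (required for "emt" and "bloch"; EMT permittivities
#'   are derived from the cell's materials and fill fraction)
#' @param polarization "TM" or "TE" (Bloch only; EMT is the TM extraordinary
#'   wave)
#' @return data.frame with columns `kx_over_k0`, `kz_re`, `kz_im`
#'   (both normalized to k0) and attribute `model`
#' @export
isofrequency_curve <- function(model = c("air", "emt", "bloch"),
                               kx_over_k0, wavelength, cell = NULL,
                               polarization = "TM") {
  model <- match.arg(model)
  stopifnot(all(is.finite(kx_over_k0)))
  k0 <- 2 * pi / wavelength
  kz <- switch(model,
    air = {
      v <- sqrt(as.complex(1 - kx_over_k0^2))
      ifelse(Im(v) < 0, -v, v)
    },
    emt = {
      stopifnot(inherits(cell, "unit_cell"))
      emt <- emt_permittivities(cell$fill,
                                permittivity(cell$material_1, wavelength),
                                permittivity(cell$material_2, wavelength))
      v <- sqrt(emt$eps_parallel * (1 - kx_over_k0^2 / emt$eps_perp))
      ## display convention: forward phase (Re >= 0); on the evanescent
      ## branch (Re ~ 0) pick decaying waves, Im >= 0
      v <- ifelse(Re(v) < 0, -v, v)
      ifelse(abs(Re(v)) < 1e-9 & Im(v) < 0, -v, v)
    },
    bloch = {
      stopifnot(inherits(cell, "unit_cell"))
      bloch_kz(cell, wavelength, kx_over_k0 * k0, polarization) / k0
    })
  out <- data.frame(kx_over_k0 = kx_over_k0, kz_re = Re(kz), kz_im = Im(kz))
  attr(out, "model") <- model
  attr(out, "wavelength") <- wavelength
  out
}

#' Largest in-plane wavevector supported by a periodic multilayer
#'
#' Scans \eqn{k_\parallel/k_0} from 0 to the Brillouin-zone edge
#' \eqn{\pi/(\Lambda k_0)} and returns the largest value whose TM Bloch mode
#' is still "propagating" in the attenuation sense
#' \eqn{Im(K)\Lambda <} `attenuation_threshold`.
#'
#' @param cell a `unit_cell`
#' @param wavelength vacuum wavelength [nm]
#' @param attenuation_threshold per-period attenuation criterion, default 1
#' @param step scan step in units of k0, default 0.05
#' @param polarization "TM" (default) or "TE"
#' @return largest supported \eqn{k_\parallel/k_0}; 0 with a warning when no
#'   scanned wavevector satisfies the criterion
#' @examples
#' \donttest{
#' cell <- unit_cell(ag_material(), 10, silica_material(), 10)
#' max_k_support(cell, 488)  # about 9-10 k0
#' }
#' @export
max_k_support <- function(cell, wavelength, attenuation_threshold = 1,
                          step = 0.05, polarization = "TM") {
  stopifnot(attenuation_threshold > 0)
  k0 <- 2 * pi / wavelength
  k_edge <- pi / (cell$period * k0)
  krel <- seq(0, k_edge, by = step)
  K <- bloch_kz(cell, wavelength, krel * k0, polarization)
  ok <- Im(K) * cell$period < attenuation_threshold
  ok[is.na(ok)] <- FALSE   # degenerate points (e.g. kz = 0 in both layers)
  if (!any(ok)) {
    warning("no scanned k_parallel satisfies the attenuation criterion")
    return(0)
  }
  max(krel[ok])
}

#' Structured-illumination resolution budget
#'
#' The detectable spatial-frequency support of a linear SIM system is the sum
#' of the detection cutoff and the illumination-pattern cutoff,
#' \eqn{f = f_{det} + f_{illum}}, with \eqn{f_{det} = 2 NA_{det}/\lambda_{det}}
#' and \eqn{f_{illum} = 2 k_{illum}^{max}/\lambda_{illum}} (intensity-pattern
#' cutoff, with the illumination bound expressed in units of its k0).
#'
#' @param na_det detection numerical aperture
#' @param lambda_det emission wavelength [nm]
#' @param k_illum_max illumination bound in units of the illumination k0
#'   (0 for plain widefield; 1 for a diffraction-limited standing wave)
#' @param lambda_illum excitation wavelength [nm]
#' @return list of class `resolution_budget` with `f_det`, `f_illum`, `f`
#'   [cycles/nm], `min_period` = 1/f [nm], and `ratio` = f/f_det
#' @examples
#' b <- resolution_budget(1.5, 520, k_illum_max = 10, lambda_illum = 488)
#' b$min_period  # nm
#' @export
resolution_budget <- function(na_det, lambda_det, k_illum_max = 0,
                              lambda_illum = lambda_det) {
  stopifnot(na_det > 0, k_illum_max >= 0)
  f_det <- 2 * na_det / lambda_det
  f_illum <- 2 * k_illum_max / lambda_illum
  f <- f_det + f_illum
  structure(list(f_det = f_det, f_illum = f_illum, f = f,
                 min_period = 1 / f, ratio = f / f_det),
            class = "resolution_budget")
}

#' @export
print.resolution_budget <- function(x, ...) {
  cat(sprintf(
    "<resolution_budget> f_det = %.4g, f_illum = %.4g, f = %.4g cycles/nm\n",
    x$f_det, x$f_illum, x$f))
  cat(sprintf("  min resolvable period = %.3g nm (gain over detection: %.3g)\n",
              x$min_period, x$ratio))
  invisible(x)
}
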