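#' Planar layer stacks
#'
#' A `layer_stack` describes a stratified optical system: a semi-infinite
#' superstrate (incidence side), an ordered list of finite layers, and a
#' semi-infinite substrate. Layer order runs from the incidence side towards
#' the substrate.
#'
#' @param layers list of `list(material = <optical_material>, thickness = nm)`
#' @param superstrate,substrate `optical_material`s; default air above,
#'   glass (n = 1.52) below
#' @return object of class `layer_stack`
#' @examples
#' hmm_stack()  # 3 pairs of 10 nm Ag / 4 nm SiO2 on glass
#' @export
layer_stack <- function(layers = list(), superstrate = air_material(),
                        substrate = glass_material()) {
  for (ly in layers) {
    stopifnot(inherits(ly$material, "optical_material"))
    if (!is.finite(ly$thickness) || ly$thickness <= 0)
      stop("layer thicknesses must be finite and positive")
  }
  structure(list(superstrate = superstrate, layers = layers,
                 substrate = substrate),
            class = "layer_stack")
}

#' The Ag/SiO2 hyperbolic-metamaterial stack
#'
#' `n_pairs` repetitions of {`d_metal` nm Ag / `d_diel` nm SiO2} on a glass
#' substrate, air above. Defaults reproduce the 3-pair {10 nm Ag / 4 nm SiO2}
#' multilayer.
#'
#' @param n_pairs number of metal/dielectric pairs
#' @param d_metal,d_diel layer thicknesses [nm]
#' @param metal,dielectric materials; default bundled Ag table and SiO2 1.46
#' @param substrate substrate material, default glass n = 1.52
#' @return a `layer_stack`
#' @export
hmm_stack <- function(n_pairs = 3, d_metal = 10, d_diel = 4,
                      metal = ag_material(), dielectric = silica_material(),
                      substrate = glass_material()) {
  layers <- vector("list", 2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    layers[[2L * i - 1L]] <- list(material = metal, thickness = d_metal)
    layers[[2L * i]] <- list(material = dielectric, thickness = d_diel)
  }
  layer_stack(layers, substrate = substrate)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack>", length(x$layers), "layers;",
      x$superstrate$name, "/",
      paste(vapply(x$layers, function(l)
        paste0(l$material$name, " ", l$thickness, "nm"), ""), collapse = " | "),
      "/", x$substrate$name, "\n")
  invisible(x)
}

## Layer-normal wavevector, principal branch Im(kz) >= 0.
#' @keywords internal
kz_layer <- function(eps, k0, k_parallel) {
  kz <- sqrt(as.complex(eps * k0^2 - k_parallel^2))
  ifelse(Im(kz) < 0, -kz, kz)
}

#' Transfer-matrix reflection and transmission of a layer stack
#'
#' Exact plane-wave solution for a stratified medium. Power transmittance
#' includes the ratio of normal power flux in substrate vs superstrate
#' (Re(kz/eps) for TM, Re(kz) for TE), so R + T + A = 1 with A the absorbed
#' fraction.
#'
#' @param stack a `layer_stack`
#' @param wavelength vacuum wavelength [nm]
#' @param k_parallel in-plane wavevector [rad/nm], real and >= 0; must not
#'   exceed the superstrate light line (propagating incidence)
#' @param polarization "TM" (p) or "TE" (s)
#' @return list with complex amplitudes `r`, `t` and power fractions
#'   `R`, `T`, `A`
#' @examples
#' # Fresnel limit: single air/glass interface at normal incidence, R = 4%
#' s <- layer_stack(substrate = constant_material("glass", 1.5))
#' tmm_coefficients(s, 500, 0, "TE")$R
#' @export
tmm_coefficients <- function(stack, wavelength, k_parallel = 0,
                             polarization = c("TM", "TE")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "layer_stack"),
            is.numeric(k_parallel), k_parallel >= 0)
  k0 <- 2 * pi / wavelength
  eps_sup <- permittivity(stack$superstrate, wavelength)
  n_sup <- sqrt(Re(eps_sup))
  if (k_parallel > n_sup * k0 + 1e-12)
    stop("evanescent incidence in the superstrate ",
         "(k_parallel > n_sup * k0): power normalization undefined")
  eps <- c(eps_sup,
           vapply(stack$layers, function(l)
             permittivity(l$material, wavelength), complex(1)),
           permittivity(stack$substrate, wavelength))
  d <- vapply(stack$layers, function(l) l$thickness, 0)
  kz <- kz_layer(eps, k0, k_parallel)
  q <- if (polarization == "TM") kz / eps else kz
  nm <- length(eps)
  M <- diag(2) + 0i
  for (j in 2:nm) {
    rj <- (q[j - 1L] - q[j]) / (q[j - 1L] + q[j])
    tj <- 2 * q[j - 1L] / (q[j - 1L] + q[j])
    M <- M %*% (matrix(c(1, rj, rj, 1), 2L, 2L) / tj)
    if (j < nm) {
      ph <- exp(1i * kz[j] * d[j - 1L])
      M <- M %*% diag(c(1 / ph, ph))
    }
  }
  r <- M[2L, 1L] / M[1L, 1L]
  t <- 1 / M[1L, 1L]
  flux <- if (polarization == "TM") {
    Re(kz[nm] / eps[nm]) / Re(kz[1L] / eps[1L])
  } else {
    Re(kz[nm]) / Re(kz[1L])
  }
  R <- Mod(r)^2
  T <- Mod(t)^2 * flux
  list(r = r, t = t, R = R, T = T, A = 1 - R - T)
}

## Amplitude transmission coefficient for arbitrary (possibly evanescent)
## in-plane wavevector. Unlike tmm_coefficients() no power normalization is
## attempted, so evanescent superstrate incidence is allowed; this is the
## linear transfer function used for near-field spectra.
#' @keywords internal
tmm_amplitude <- function(stack, wavelength, k_parallel,
                          polarization = "TM") {
  k0 <- 2 * pi / wavelength
  eps <- c(permittivity(stack$superstrate, wavelength),
           vapply(stack$layers, function(l)
             permittivity(l$material, wavelength), complex(1)),
           permittivity(stack$substrate, wavelength))
  d <- vapply(stack$layers, function(l) l$thickness, 0)
  kz <- kz_layer(eps, k0, k_parallel)
  q <- if (polarization == "TM") kz / eps else kz
  nm <- length(eps)
  M <- diag(2) + 0i
  for (j in 2:nm) {
    rj <- (q[j - 1L] - q[j]) / (q[j - 1L] + q[j])
    tj <- 2 * q[j - 1L] / (q[j - 1L] + q[j])
    M <- M %*% (matrix(c(1, rj, rj, 1), 2L, 2L) / tj)
    if (j < nm) {
      ph <- exp(1i * kz[j] * d[j - 1L])
      M <- M %*% diag(c(1 / ph, ph))
    }
  }
  1 / M[1L, 1L]
}

#' Transmission/reflection spectra of a stack
#'
#' Convenience wrapper evaluating [tmm_coefficients()] over a wavelength grid
#' at fixed incidence.
#'
#' @inheritParams tmm_coefficients
#' @param wavelengths vector of vacuum wavelengths [nm]
#' @return data.frame with columns `wavelength`, `R`, `T`, `A`
#' @export
tmm_spectrum <- function(stack, wavelengths, k_parallel = 0,
                         polarization = "TM") {
  rows <- lapply(wavelengths, function(wl) {
    co <- tmm_coefficients(stack, wl, k_parallel, polarization)
    data.frame(wavelength = wl, R = co$R, T = co$T, A = co$A)
  })
  do.call(rbind, rows)
}
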