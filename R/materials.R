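#' Optical materials
#'
#' An `optical_material` is either a constant-index material (non-dispersive,
#' \eqn{\epsilon = n^2}) or a tabulated dispersive material interpolated
#' linearly in (n, k) between tabulated wavelengths. The time convention is
#' \eqn{e^{-i\omega t}}, so passive materials have \eqn{Im(\epsilon) \ge 0}.
#'
#' @param name material name used in messages
#' @param n real refractive index (constant-index materials)
#' @param wavelength tabulated vacuum wavelengths [nm], strictly increasing
#' @param n_k two-column matrix or data.frame of (n, k) at those wavelengths
#' @return an object of class `optical_material`
#' @examples
#' silica <- constant_material("SiO2", 1.46)
#' permittivity(silica, 488)  # 2.1316
#' @export
constant_material <- function(name, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 0)
  structure(list(name = name, type = "constant", n = n),
            class = "optical_material")
}

#' @rdname constant_material
#' @export
tabulated_material <- function(name, wavelength, n_k) {
  n_k <- as.matrix(n_k)
  stopifnot(length(wavelength) == nrow(n_k), ncol(n_k) == 2L)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing for material '", name, "'")
  if (any(n_k[, 2L] < 0))
    stop("k must be >= 0 (passive material, e^{-i w t} convention)")
  structure(list(name = name, type = "table",
                 wavelength = as.numeric(wavelength),
                 n = as.numeric(n_k[, 1L]), k = as.numeric(n_k[, 2L])),
            class = "optical_material")
}

#' Built-in materials
#'
#' `ag_material()` loads the bundled tabulation of silver optical constants
#' (Johnson & Christy, Phys. Rev. B 6, 4370, 1972). `silica_material()`,
#' `glass_material()` and `air_material()` are the constant-index defaults
#' used for the Ag/SiO2 multilayer on a coverslip: n = 1.46, 1.52 and 1.
#'
#' @return an `optical_material`
#' @export
ag_material <- function() {
  path <- system.file("extdata", "ag_johnson_christy.txt",
                      package = "specklemain", mustWork = TRUE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("wavelength", "n", "k"))
  tab <- tab[order(tab$wavelength), ]
  tabulated_material("Ag (Johnson & Christy 1972)", tab$wavelength,
                     tab[, c("n", "k")])
}

#' @rdname ag_material
#' @export
silica_material <- function() constant_material("SiO2", 1.46)

#' @rdname ag_material
#' @export
glass_material <- function() constant_material("glass", 1.52)

#' @rdname ag_material
#' @export
air_material <- function() constant_material("air", 1)

#' Complex relative permittivity at a wavelength
#'
#' Interpolates (n, k) linearly within the tabulated range and returns
#' \eqn{\epsilon = (n + ik)^2}; constant-index materials return \eqn{n^2}
#' at any positive wavelength.
#'
#' @param material an `optical_material`
#' @param wavelength vacuum wavelength [nm]; may be a vector
#' @return complex permittivity (vectorized over `wavelength`)
#' @export
permittivity <- function(material, wavelength) {
  stopifnot(inherits(material, "optical_material"), all(wavelength > 0))
  if (material$type == "constant") {
    return(rep(complex(real = material$n^2), length(wavelength)))
  }
  rng <- range(material$wavelength)
  if (any(wavelength < rng[1L] | wavelength > rng[2L]))
    stop("wavelength outside tabulated range [", round(rng[1L], 1), ", ",
         round(rng[2L], 1), "] nm for material '", material$name, "'")
  n <- stats::approx(material$wavelength, material$n, wavelength)$y
  k <- stats::approx(material$wavelength, material$k, wavelength)$y
  (complex(real = n, imaginary = k))^2
}

#' @export
print.optical_material <- function(x, ...) {
  if (x$type == "constant") {
    cat("<optical_material>", x$name, " n =", x$n, "\n")
  } else {
    cat("<optical_material>", x$name, " tabulated,",
        length(x$wavelength), "points,",
        round(min(x$wavelength)), "-", round(max(x$wavelength)), "nm\n")
  }
  invisible(x)
}
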