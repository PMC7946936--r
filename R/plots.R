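## Base-graphics display methods for the package's image-like objects.

#' @keywords internal
show_image <- function(mat, dx, main = "", col = grDevices::gray.colors(256),
                       ...) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  graphics::image(x = (0:(n1 - 1)) * dx, y = (0:(n2 - 1)) * dx,
                  z = mat, asp = 1, col = col, xlab = "x [nm]",
                  ylab = "y [nm]", main = main, useRaster = TRUE, ...)
}

#' @export
plot.speckle_pattern <- function(x, ...) {
  show_image(x$intensity, x$dx,
             main = sprintf("speckle |E|^2 (lambda = %g nm, z = %g nm)",
                            x$wavelength, x$z), ...)
  invisible(x)
}

#' @export
plot.height_map <- function(x, ...) {
  show_image(x$heights, x$dx, main = "surface height [nm]", ...)
  invisible(x)
}

#' @export
plot.scene <- function(x, ...) {
  show_image(x$density, x$dx_f, main = "fluorophore density", ...)
  invisible(x)
}

#' @export
plot.recon_result <- function(x, which = c("object", "cost"), ...) {
  which <- match.arg(which)
  if (which == "object") {
    show_image(x$rho, x$dx, main = "blind-SIM object estimate", ...)
  } else {
    graphics::plot(seq_along(x$cost) - 1, x$cost, type = "l",
                   xlab = "iteration", ylab = "objective", log = "y", ...)
  }
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, criterion = 1 / 7, ...) {
  graphics::plot(x$freq, x$frc, type = "l", ylim = c(min(0, min(x$frc)), 1),
                 xlab = "spatial frequency [1/nm]", ylab = "FRC", ...)
  graphics::abline(h = criterion, lty = 2)
  res <- frc_resolution(x, criterion)
  if (!res$no_crossing)
    graphics::abline(v = res$crossing_freq, lty = 3)
  invisible(x)
}

#' Isofrequency curve comparison plot
#'
#' Overlays the air, EMT and Bloch isofrequency curves of a unit cell at one
#' wavelength (real parts of kz, both axes in units of k0).
#'
#' @param cell a `unit_cell`
#' @param wavelength vacuum wavelength [nm]
#' @param kx_max plot range in k0 units
#' @export
plot_isofrequency <- function(cell, wavelength, kx_max = 12) {
  kx <- seq(0, kx_max, length.out = 400)
  air <- isofrequency_curve("air", kx, wavelength)
  emt <- isofrequency_curve("emt", kx, wavelength, cell)
  blo <- isofrequency_curve("bloch", kx, wavelength, cell)
  graphics::plot(air$kx_over_k0, air$kz_re, type = "l",
                 xlim = c(0, kx_max), ylim = c(0, max(blo$kz_re, 2)),
                 xlab = expression(k[x] / k[0]),
                 ylab = expression(Re(k[z]) / k[0]))
  graphics::lines(emt$kx_over_k0, emt$kz_re, col = 2)
  graphics::lines(blo$kx_over_k0, blo$kz_re, col = 4)
  graphics::legend("topright", legend = c("air", "EMT", "Bloch"),
                   col = c(1, 2, 4), lty = 1, bty = "n")
  invisible(NULL)
}
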