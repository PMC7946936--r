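## TIFF + YAML-sidecar I/O. Pixel data go into multi-page 32-bit float TIFF;
## everything TIFF cannot carry (pixel sizes, seeds, noise descriptors) goes
## into a YAML sidecar next to the image file ("<path>.yaml").

#' @keywords internal
sidecar_path <- function(path) paste0(path, ".yaml")

#' Write / read a frame stack as multi-page TIFF with YAML sidecar
#'
#' Pixel data are stored as 32-bit float TIFF pages (lossless for the
#' simulated counts); camera pixel size, noise descriptor and seeds go to a
#' YAML sidecar, so a write/read round trip reproduces the stack exactly.
#'
#' @param stack a `frame_stack`
#' @param path output TIFF path; the sidecar is written to `<path>.yaml`
#' @return `write_stack`: the path, invisibly. `read_stack`: a
#'   `frame_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  M <- dim(stack$frames)[3L]
  sc <- range01(stack$frames)
  pages <- lapply(seq_len(M), function(m) sc$x[, , m])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(dx_c = stack$dx_c, noise = stack$noise,
               seeds = as.integer(stack$seeds),
               normalized = isTRUE(stack$meta$normalized),
               dx_f = stack$meta$dx_f, binning = stack$meta$binning,
               offset = sc$offset, scale = sc$scale)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

## TIFF pages must lie in [0, 1]: affine-rescale and keep the transform in
## the sidecar (float32 quantization is the only loss).
#' @keywords internal
range01 <- function(x) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  list(x = (x - lo) / scale, offset = lo, scale = scale)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
  } else {
    warning("no metadata sidecar found for ", path, "; using defaults")
    meta <- list(dx_c = 1, noise = list(), seeds = seq_along(pages))
  }
  if (!is.null(meta$scale)) frames <- frames * meta$scale + meta$offset
  structure(list(frames = frames,
                 dx_c = if (is.null(meta$dx_c)) 1 else meta$dx_c,
                 noise = if (is.null(meta$noise)) list() else meta$noise,
                 seeds = meta$seeds,
                 meta = list(dx_f = meta$dx_f, binning = meta$binning,
                             normalized = isTRUE(meta$normalized))),
            class = "frame_stack")
}

#' Write / read a single image (32-bit float TIFF + sidecar)
#'
#' @param image matrix (any real values; stored as float32)
#' @param path TIFF path
#' @param dx pixel size [nm], recorded in the sidecar
#' @return `write_image`: path invisibly; `read_image`: list with `image`
#'   and `dx`
#' @export
write_image <- function(image, path, dx = 1) {
  sc <- range01(image)
  tiff::writeTIFF(sc$x, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(dx = dx, offset = sc$offset, scale = sc$scale),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else list(dx = 1)
  if (!is.null(meta$scale)) img <- img * meta$scale + meta$offset
  list(image = img, dx = meta$dx)
}

#' Export a height map as TIFF (+ sidecar with dx)
#'
#' @param map a `height_map`
#' @param path TIFF path
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  sc <- range01(map$heights)
  tiff::writeTIFF(sc$x, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(dx = map$dx, rms = map$rms,
                        corr_length = map$corr_length, seed = map$seed,
                        offset = sc$offset, scale = sc$scale),
                   sidecar_path(path))
  invisible(path)
}
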