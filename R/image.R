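## UV image container and PNG IO. Pixels are stored as numeric intensities
## on the 8-bit scale [0, 255]; grayscale images are H x W matrices, RGB
## images H x W x 3 arrays.

#' Construct a UV photograph object
#'
#' @param pixels numeric H x W matrix (gray) or H x W x 3 array (RGB) of
#'   intensities in `[0, 255]`.
#' @param meta named list of acquisition metadata; conventional fields are
#'   `participant`, `visit`, and `condition` (one of `baseline`,
#'   `sunscreen`, `moisturiser`).
#' @return Object of class `uv_image` with fields `pixels`,
#'   `channel_mode` (`"gray"` or `"rgb"`), and `meta`.
#' @export
uv_image <- function(pixels, meta = list()) {
  nd <- length(dim(pixels))
  if (nd == 2L) mode <- "gray"
  else if (nd == 3L && dim(pixels)[3L] == 3L) mode <- "rgb"
  else stop("unsupported channel count: pixels must be HxW or HxWx3")
  if (any(pixels < 0 | pixels > 255, na.rm = TRUE)) {
    stop("pixel intensities must lie in [0, 255]")
  }
  structure(list(pixels = pixels, channel_mode = mode, meta = meta),
            class = "uv_image")
}

#' @export
print.uv_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<uv_image %dx%d %s%s>\n", d[1L], d[2L], x$channel_mode,
              if (length(x$meta)) paste0(" [", paste(names(x$meta),
                unlist(x$meta), sep = "=", collapse = ", "), "]") else ""))
  invisible(x)
}

#' @rdname uv_image
#' @export
image_dims <- function(pixels) dim(pixels$pixels)[1:2]

#' Write a `uv_image` as an 8-bit PNG
#'
#' @param img a [uv_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uv_png <- function(img, path) {
  stopifnot(inherits(img, "uv_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Read a PNG (or single-plane TIFF-like gray PNG) as a `uv_image`
#'
#' Intensities are rescaled to the 8-bit range and rounded, so an image
#' written by [write_uv_png()] round-trips pixel-identically.
#'
#' @param path PNG path.
#' @param meta metadata list attached to the image.
#' @return A [uv_image()].
#' @export
read_uv_png <- function(path, meta = list()) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3L] == 4L) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3L] == 2L) px <- px[, , 1L]   # gray+alpha
  uv_image(round(px * 255), meta = meta)
}
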