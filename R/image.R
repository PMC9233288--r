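# Image containers and I/O.
#
# Images are plain numeric arrays in [0, 1]: height x width (grayscale) or
# height x width x 3 (RGB), row 1 = top of the image. Points are (x, y) pairs
# with x = column and y = row, 1-based. EBImage (which indexes [x, y]) is used
# behind connected-component labelling only; conversions are kept local.

#' Construct a raw scan object
#'
#' A `raw_scan` wraps an RGB raster as it comes off the scanner, before any
#' geometric normalization. Rasters must be at least 200 x 200 px with exactly
#' three channels.
#'
#' @param pixels numeric array `height x width x 3` with values in `[0, 1]`
#'   (values in `0..255` are rescaled).
#' @param source_id opaque identifier (file name, accession id, ...).
#' @param dpi_hint optional positive scan resolution hint.
#' @return object of class `raw_scan`.
#' @export
raw_scan <- function(pixels, source_id = "scan", dpi_hint = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    iop_error("InputError", "raw_scan: pixels must be a height x width x 3 array")
  if (dim(pixels)[1] < 200L || dim(pixels)[2] < 200L)
    iop_error("InputError", "raw_scan: image must be at least 200 x 200 px")
  if (max(pixels) > 1) pixels <- pixels / 255
  if (!is.null(dpi_hint) && (!is.numeric(dpi_hint) || dpi_hint <= 0))
    iop_error("InputError", "raw_scan: dpi_hint must be a positive number")
  structure(list(pixels = pixels, source_id = as.character(source_id),
                 dpi_hint = dpi_hint),
            class = "raw_scan")
}

#' Read a chart scan from PNG, TIFF or JPEG
#'
#' @param path image file path; format inferred from the extension.
#' @param dpi_hint optional resolution hint stored on the scan.
#' @return a [raw_scan()].
#' @export
read_scan <- function(path, dpi_hint = NULL) {
  if (!file.exists(path))
    iop_error("InputError", paste0("read_scan: no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        iop_error("InputError", "read_scan: the 'jpeg' package is required for JPEG input")
      jpeg::readJPEG(path)
    },
    iop_error("InputError", paste0("read_scan: unsupported image format: .", ext))
  )
  px <- ensure_rgb(px)
  raw_scan(px, source_id = basename(path), dpi_hint = dpi_hint)
}

#' Write an RGB or grayscale raster as PNG
#'
#' @param pixels image array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(clamp01(pixels), path)
  invisible(path)
}

# Promote grayscale / RGBA to 3-channel RGB.
ensure_rgb <- function(px) {
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    iop_error("InputError", "expected a grayscale, RGB or RGBA raster")
  px
}

#' Convert an RGB raster to grayscale
#'
#' Uses the standard Rec. 601 luma weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param pixels RGB array or a [raw_scan()] / [canonical_chart] object.
#' @return numeric matrix in `[0, 1]`.
#' @export
to_gray <- function(pixels) {
  px <- chart_pixels(pixels)
  if (is.matrix(px)) return(px)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# Accept raw arrays or the package's wrapper objects.
chart_pixels <- function(x) {
  if (inherits(x, "raw_scan") || inherits(x, "canonical_chart")) x$pixels else x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Connected-component labelling via EBImage; input logical matrix [y, x],
# output integer matrix of the same shape (0 = background).
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  t(EBImage::imageData(lab))
}

#' Resize an image by bilinear resampling
#'
#' @param pixels grayscale matrix or RGB array.
#' @param scale scale factor (> 0); 2 doubles the resolution.
#' @return resampled image.
#' @export
resize_image <- function(pixels, scale) {
  d <- dim(pixels)
  nh <- max(2L, round(d[1] * scale)); nw <- max(2L, round(d[2] * scale))
  ys <- seq(1, d[1], length.out = nh)
  xs <- seq(1, d[2], length.out = nw)
  out <- bilinear_sample(pixels, rep(xs, each = nh), rep(ys, times = nw), fill = 1)
  dim(out) <- if (length(d) == 2L) c(nh, nw) else c(nh, nw, d[3])
  out
}

#' @export
print.raw_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<raw_scan> ", x$source_id, ": ", d[2], " x ", d[1], " px",
      if (!is.null(x$dpi_hint)) paste0(", ~", x$dpi_hint, " dpi"), "\n", sep = "")
  invisible(x)
}
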