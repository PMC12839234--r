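#' Read a grayscale image as a normalized intensity matrix
#'
#' Reads an 8-bit PNG or an 8/16-bit TIFF and returns intensities divided by
#' the format's full-scale maximum (255 or 65535), so the result lies in
#' \[0, 1\] regardless of the image content. Multi-channel files are rejected:
#' the network is single-channel by construction and colour inputs must be
#' split upstream.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (rows = image height) with values in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_invalid("path must be a single file path")
  if (!file.exists(path)) stop_invalid("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid("unsupported image format '.", ext, "' (expected PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      stop_invalid("multi-channel image (", dim(img)[3],
                   " channels): single-channel grayscale required")
    }
  }
  # readPNG/readTIFF already divide by the bit-depth full scale
  check_image(img, arg = path)
  img
}

#' Write a normalized intensity matrix to an 8- or 16-bit image file
#'
#' Intensities are quantized as `round(x * (2^bit_depth - 1))` using R's
#' round-half-even rule, a fixed convention that keeps the
#' write-then-read round trip within half a quantization step.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param path Output path; `.png` (8-bit only) or `.tif`/`.tiff`.
#' @param bit_depth 8 or 16.
#' @return Invisibly, the output path.
#' @export
write_image <- function(image, path, bit_depth = 8L) {
  check_image(image)
  if (!bit_depth %in% c(8L, 16L)) stop_invalid("bit_depth must be 8 or 16")
  full <- 2^bit_depth - 1
  q <- round(image * full) / full  # round-half-even, then back to [0,1]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8L)
      stop_invalid("PNG output is 8-bit only; use TIFF for 16-bit")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bit_depth))
  } else {
    stop_invalid("unsupported output format '.", ext, "'")
  }
  invisible(path)
}
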