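#' Read and write 8-bit grayscale images and masks
#'
#' Images are stored as 8-bit grayscale PNG or TIFF (chosen by extension);
#' in R they are numeric matrices with intensities in \[0, 255\]. Masks use
#' the same containers with pixel values \{0, 255\} on disk and \{0, 1\} in R.
#'
#' @param image Numeric matrix in \[0, 255\] (`write_image`) or binary matrix
#'   (`write_mask`).
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_image`/`read_mask` return a matrix; the writers return
#'   `path` invisibly.
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_image <- function(image, path) {
  check_gray_image(image)
  scaled <- image / 255
  switch(file_ext(path),
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8),
    abort("Unsupported image extension (use .png/.tif/.tiff).")
  )
  invisible(path)
}

#' @rdname image_io
#' @export
read_image <- function(path) {
  raw <- switch(file_ext(path),
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort("Unsupported image extension (use .png/.tif/.tiff).")
  )
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  round(raw * 255)
}

#' @rdname image_io
#' @export
write_mask <- function(image, path) {
  check_mask(image)
  write_image(image * 255, path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  (img >= 128) * 1
}

file_ext <- function(path) tolower(sub(".*\\.", "", path))
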