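#' Data-augmentation operators for grayscale images
#'
#' Deterministic geometric and photometric transforms of the kind used to
#' enlarge ultrasound training sets: cropping, zooming, rotation, and
#' brightness/contrast adjustment. All outputs are clipped to \[0, 255\].
#'
#' Rotations by multiples of 90 degrees are exact index permutations (no
#' interpolation); other angles use nearest-neighbour inverse mapping about
#' the image centre with background fill 0, preserving the image dimensions.
#' Zooming uses nearest-neighbour resampling, so a zoomed image contains only
#' intensities present in the input.
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param op One of `"crop"`, `"zoom"`, `"rotate"`, `"brightness"`,
#'   `"contrast"`.
#' @param box For `crop`: integer vector `c(row1, col1, row2, col2)`, the
#'   inclusive crop box; must lie inside the image.
#' @param factor For `zoom`: size multiplier > 0. For `contrast`: gain applied
#'   about mid-gray 127.5.
#' @param degrees For `rotate`: counter-clockwise angle in degrees.
#' @param offset For `brightness`: additive intensity shift.
#'
#' @return Transformed matrix with intensities in \[0, 255\].
#' @examples
#' img <- matrix(runif(64, 0, 255), 8, 8)
#' identical(augment(img, "rotate", degrees = 0), img)
#' augment(img, "brightness", offset = 20)[1, 1] - img[1, 1]
#' @export
augment <- function(image, op = c("crop", "zoom", "rotate", "brightness", "contrast"),
                    box = NULL, factor = 1, degrees = 0, offset = 0) {
  check_gray_image(image)
  op <- match.arg(op)
  switch(op,
    crop = aug_crop(image, box),
    zoom = aug_zoom(image, factor),
    rotate = aug_rotate(image, degrees),
    brightness = clip255(image + offset),
    contrast = clip255((image - 127.5) * factor + 127.5)
  )
}

aug_crop <- function(image, box) {
  if (is.null(box) || length(box) != 4) {
    abort("`box` must be c(row1, col1, row2, col2).")
  }
  box <- as.integer(box)
  if (box[1] < 1 || box[2] < 1 || box[3] > nrow(image) || box[4] > ncol(image) ||
      box[1] > box[3] || box[2] > box[4]) {
    abort("Crop box must lie inside the image.")
  }
  image[box[1]:box[3], box[2]:box[4], drop = FALSE]
}

aug_zoom <- function(image, factor) {
  if (!is.numeric(factor) || factor <= 0) abort("Zoom `factor` must be > 0.")
  nr <- max(1L, as.integer(round(nrow(image) * factor)))
  nc <- max(1L, as.integer(round(ncol(image) * factor)))
  rows <- pmin(pmax(as.integer(ceiling(seq_len(nr) / factor)), 1L), nrow(image))
  cols <- pmin(pmax(as.integer(ceiling(seq_len(nc) / factor)), 1L), ncol(image))
  image[rows, cols, drop = FALSE]
}

aug_rotate <- function(image, degrees) {
  degrees <- degrees %% 360
  if (degrees %% 90 == 0) {
    k <- (degrees %/% 90) %% 4
    out <- image
    for (q in seq_len(k)) {
      # one exact counter-clockwise quarter turn
      out <- t(out)[rev(seq_len(ncol(out))), , drop = FALSE]
    }
    return(out)
  }
  theta <- degrees * pi / 180
  nr <- nrow(image)
  nc <- ncol(image)
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  out <- matrix(0, nr, nc)
  grid <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  # inverse mapping: rotate output coordinates back into the source image
  di <- grid$i - cr
  dj <- grid$j - cc
  src_i <- round(cr + cos(theta) * di + sin(theta) * dj)
  src_j <- round(cc - sin(theta) * di + cos(theta) * dj)
  ok <- src_i >= 1 & src_i <= nr & src_j >= 1 & src_j <= nc
  out[cbind(grid$i[ok], grid$j[ok])] <- image[cbind(src_i[ok], src_j[ok])]
  out
}
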