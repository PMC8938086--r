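#' Window statistics for adaptive median filtering
#'
#' Computes the minimum, maximum and median intensity of an `m` x `n`
#' rectangular window centred on a pixel, together with the centre intensity
#' itself. Pixels outside the image are filled by edge replication, so every
#' centre position has a full window.
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param center Integer vector `c(row, col)` of the window centre; must lie
#'   inside the image.
#' @param m,n Odd window height and width, in pixels.
#'
#' @return A named list with elements `z_min`, `z_max`, `z_med` and `z_xy`
#'   (the centre intensity). The median of an odd number of values is always
#'   one of the window's values.
#' @examples
#' img <- matrix(1:9, 3, 3, byrow = TRUE)
#' window_stats(img, c(2, 2), 3, 3)
#' @export
window_stats <- function(image, center, m, n) {
  check_gray_image(image)
  if (!is_odd(m) || !is_odd(n)) {
    abort("Window dimensions `m` and `n` must both be odd.")
  }
  i <- as.integer(center[1])
  j <- as.integer(center[2])
  if (i < 1 || i > nrow(image) || j < 1 || j > ncol(image)) {
    abort("`center` must lie inside the image.")
  }
  hm <- (m - 1) / 2
  hn <- (n - 1) / 2
  rows <- pmin(pmax(i + (-hm:hm), 1), nrow(image))
  cols <- pmin(pmax(j + (-hn:hn), 1), ncol(image))
  win <- image[rows, cols, drop = FALSE]
  list(
    z_min = min(win),
    z_max = max(win),
    z_med = median(win),
    z_xy  = image[i, j]
  )
}

#' Level A decision of the adaptive median filter
#'
#' Tests whether the window median is strictly between the window extremes,
#' i.e. whether `z_med - z_min > 0` and `z_max - z_med > 0`. Only then can the
#' median be trusted not to be an impulse, and the filter proceeds to the
#' Level B decision; otherwise the window must be enlarged.
#'
#' @param z_min,z_max,z_med Window minimum, maximum and median.
#' @return `"go_to_level_b"` or `"enlarge_window"`.
#' @examples
#' level_a(1, 9, 5) # "go_to_level_b"
#' level_a(0, 9, 0) # median equals minimum: possibly an impulse
#' @export
level_a <- function(z_min, z_max, z_med) {
  if ((z_med - z_min) > 0 && (z_max - z_med) > 0) "go_to_level_b" else "enlarge_window"
}

#' Level B output of the adaptive median filter
#'
#' Given a trusted window median, keeps the centre pixel if it is itself
#' strictly between the window extremes (`z_xy - z_min > 0` and
#' `z_max - z_xy > 0`); a centre pixel equal to either extreme is treated as
#' an impulse and replaced by the window median.
#'
#' @inheritParams level_a
#' @param z_xy Centre pixel intensity.
#' @return The output intensity for the pixel.
#' @examples
#' level_b(1, 9, 5, 4) # centre kept
#' level_b(1, 9, 5, 9) # centre is the window max: replaced by the median
#' @export
level_b <- function(z_min, z_max, z_med, z_xy) {
  if ((z_xy - z_min) > 0 && (z_max - z_xy) > 0) z_xy else z_med
}

#' Adaptive median filter for impulse-corrupted grayscale images
#'
#' Per-pixel two-stage filter for salt-and-pepper ("long-tail") noise. For
#' each pixel a square window starts at `initial_size` and grows by 2 per
#' side while the Level A test fails, up to `s_max`; if Level A never passes
#' the original centre value is output, otherwise Level B decides between the
#' centre value and the window median. Each output pixel depends only on the
#' original image, so the result is independent of scan order, and every
#' output value is a value present in the (edge-replicated) input.
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param initial_size Odd starting window size (default 3).
#' @param s_max Odd maximum window size (default 7); must be >= `initial_size`.
#' @return Filtered matrix, same dimensions as `image`.
#' @examples
#' img <- matrix(10, 7, 7)
#' img[4, 4] <- 255
#' filtered <- adaptive_median_filter(img)
#' filtered[4, 4] # impulse removed
#' @export
adaptive_median_filter <- function(image, initial_size = 3L, s_max = 7L) {
  check_gray_image(image)
  if (!is_odd(initial_size) || !is_odd(s_max)) {
    abort("`initial_size` and `s_max` must both be odd.")
  }
  if (initial_size < 1 || s_max < initial_size) {
    abort("Require 1 <= `initial_size` <= `s_max`.")
  }
  nr <- nrow(image)
  nc <- ncol(image)
  pad <- (s_max - 1L) / 2L
  padded <- pad_replicate(image, pad)
  out <- image
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      w <- initial_size
      z_xy <- image[i, j]
      repeat {
        h <- (w - 1L) / 2L
        win <- padded[(i + pad - h):(i + pad + h), (j + pad - h):(j + pad + h)]
        z_min <- min(win)
        z_max <- max(win)
        z_med <- median(win)
        if ((z_med - z_min) > 0 && (z_max - z_med) > 0) {
          out[i, j] <- if ((z_xy - z_min) > 0 && (z_max - z_xy) > 0) z_xy else z_med
          break
        }
        if (w >= s_max) {
          out[i, j] <- z_xy
          break
        }
        w <- w + 2L
      }
    }
  }
  out
}

# edge-replication padding by `pad` pixels on every side
pad_replicate <- function(image, pad) {
  if (pad == 0) return(image)
  rows <- c(rep(1L, pad), seq_len(nrow(image)), rep(nrow(image), pad))
  cols <- c(rep(1L, pad), seq_len(ncol(image)), rep(ncol(image), pad))
  image[rows, cols, drop = FALSE]
}
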