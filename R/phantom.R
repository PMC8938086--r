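#' Configuration for a synthetic ultrasound phantom
#'
#' Describes a two-level lesion phantom and its noise model. The clean image
#' is a uniform background with an elliptical (or radially perturbed
#' "irregular blob") lesion; the corrupted image applies mean-one log-normal
#' multiplicative speckle followed by salt-and-pepper impulse noise, the
#' standard simple stand-ins for the multiplicative and long-tail noise of
#' B-mode imaging.
#'
#' @param height,width Image dimensions in pixels (>= 8).
#' @param lesion_shape `"ellipse"` or `"irregular_blob"`.
#' @param center Lesion centre `c(row, col)`; defaults to the image centre.
#' @param axes Lesion semi-axes `c(row, col)` in pixels; default one fifth of
#'   each image dimension.
#' @param boundary_amplitude Relative amplitude of the random radial boundary
#'   perturbation used by `"irregular_blob"` (0 gives an exact ellipse).
#' @param background_level,lesion_level Clean-image intensities in \[0, 255\].
#'   The default lesion is hypoechoic (darker than the surrounding liver).
#' @param speckle_scale Standard deviation of log-intensity speckle; 0
#'   disables speckle.
#' @param impulse_density Fraction of pixels replaced by salt (255) or pepper
#'   (0), split evenly; 0 disables impulse noise.
#' @param seed Integer seed; identical configs are bit-reproducible.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(height = 128, width = 128,
                           lesion_shape = c("ellipse", "irregular_blob"),
                           center = NULL, axes = NULL,
                           boundary_amplitude = 0.15,
                           background_level = 120, lesion_level = 60,
                           speckle_scale = 0.2, impulse_density = 0.05,
                           seed = 1L) {
  height <- check_count(height, "height", min = 8)
  width <- check_count(width, "width", min = 8)
  lesion_shape <- match.arg(lesion_shape)
  center <- center %||% c((height + 1) / 2, (width + 1) / 2)
  axes <- axes %||% c(height / 5, width / 5)
  if (any(axes <= 0)) abort("Lesion `axes` must be positive.")
  check_prob(impulse_density, "impulse_density")
  if (background_level < 0 || background_level > 255 ||
      lesion_level < 0 || lesion_level > 255) {
    abort("Intensity levels must lie in [0, 255].")
  }
  if (speckle_scale < 0) abort("`speckle_scale` must be >= 0.")
  structure(
    list(height = height, width = width, lesion_shape = lesion_shape,
         center = center, axes = axes, boundary_amplitude = boundary_amplitude,
         background_level = background_level, lesion_level = lesion_level,
         speckle_scale = speckle_scale, impulse_density = impulse_density,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Generate a noisy lesion phantom with its ground-truth mask
#'
#' Builds the clean two-level phantom described by `config`, keeps its exact
#' lesion mask, then corrupts the image with multiplicative speckle and
#' impulse noise. With both noise terms zero the returned image equals the
#' clean phantom exactly.
#'
#' @param config A [phantom_config()].
#' @return A list with `image` (numeric matrix, \[0, 255\]), `mask` (binary
#'   matrix marking the pre-noise lesion) and `clean` (the noise-free image).
#' @examples
#' ph <- generate_phantom(phantom_config(height = 32, width = 32, seed = 7))
#' mean(ph$mask)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, {
    mask <- lesion_mask(config)
    if (sum(mask) == 0) abort("Degenerate lesion geometry: zero-area mask.")
    clean <- matrix(config$background_level, config$height, config$width)
    clean[mask == 1] <- config$lesion_level
    img <- clean
    if (config$speckle_scale > 0) {
      # mean-one log-normal multiplicative field
      s <- config$speckle_scale
      field <- exp(matrix(rnorm(length(img), -s^2 / 2, s), nrow(img)))
      img <- img * field
    }
    if (config$impulse_density > 0) {
      hit <- runif(length(img)) < config$impulse_density
      salt <- runif(length(img)) < 0.5
      img[hit & salt] <- 255
      img[hit & !salt] <- 0
    }
    img <- round(clip255(img))
    list(image = img, mask = mask, clean = clean)
  })
}

# binary lesion mask from the configured geometry; RNG is only touched by
# the irregular-blob boundary perturbation
lesion_mask <- function(config) {
  rows <- matrix(seq_len(config$height), config$height, config$width)
  cols <- matrix(seq_len(config$width), config$height, config$width, byrow = TRUE)
  dr <- (rows - config$center[1]) / config$axes[1]
  dc <- (cols - config$center[2]) / config$axes[2]
  r <- sqrt(dr^2 + dc^2)
  if (config$lesion_shape == "ellipse" || config$boundary_amplitude == 0) {
    return((r <= 1) * 1)
  }
  theta <- atan2(dc, dr)
  coef <- rnorm(8)
  wob <- config$boundary_amplitude * (
    coef[1] * cos(2 * theta) + coef[2] * sin(2 * theta) +
    (coef[3] * cos(3 * theta) + coef[4] * sin(3 * theta)) / 2 +
    (coef[5] * cos(4 * theta) + coef[6] * sin(4 * theta)) / 3 +
    (coef[7] * cos(5 * theta) + coef[8] * sin(5 * theta)) / 4)
  (r <= pmax(1 + wob, 0.05)) * 1
}
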