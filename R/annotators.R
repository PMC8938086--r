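#' Configuration for simulated annotators
#'
#' Models a panel of `k` readers who each redraw a reference lesion mask.
#' An ordinary reader's mask is the reference shifted by a random integer
#' offset (standard deviation `boundary_jitter` pixels per axis) with
#' additional random flips of boundary pixels; with probability
#' `outlier_rate` a reader is grossly discordant and places the lesion
#' elsewhere in the frame.
#'
#' @param k Number of annotators (>= 2).
#' @param boundary_jitter Pixel-scale perturbation magnitude (>= 0); 0 means
#'   every ordinary reader reproduces the reference exactly.
#' @param outlier_rate Probability that a reader is an outlier, in \[0, 1\].
#' @param seed Integer seed.
#' @return An `annotator_config` list.
#' @export
annotator_config <- function(k = 3, boundary_jitter = 1, outlier_rate = 0,
                             seed = 1L) {
  k <- check_count(k, "k", min = 2)
  if (boundary_jitter < 0) abort("`boundary_jitter` must be >= 0.")
  check_prob(outlier_rate, "outlier_rate")
  structure(
    list(k = k, boundary_jitter = boundary_jitter,
         outlier_rate = outlier_rate, seed = as.integer(seed)),
    class = "annotator_config"
  )
}

#' Simulate a panel of annotator masks
#'
#' @param mask Non-empty binary reference mask.
#' @param config An [annotator_config()].
#' @return A list of `k` binary masks (class `annotation_set`), same shape as
#'   `mask`. With `boundary_jitter = 0` and `outlier_rate = 0` all members
#'   equal the input.
#' @examples
#' ph <- generate_phantom(phantom_config(height = 32, width = 32))
#' anns <- simulate_annotators(ph$mask, annotator_config(k = 3, seed = 2))
#' length(anns)
#' @export
simulate_annotators <- function(mask, config) {
  check_mask(mask)
  stopifnot(inherits(config, "annotator_config"))
  if (sum(mask) == 0) abort("Reference `mask` must be non-empty.")
  withr::with_seed(config$seed, {
    masks <- lapply(seq_len(config$k), function(a) {
      if (runif(1) < config$outlier_rate) {
        outlier_mask(mask)
      } else {
        jitter_mask(mask, config$boundary_jitter)
      }
    })
    structure(masks, class = "annotation_set")
  })
}

# shift by integer offsets and flip boundary pixels with a jitter-dependent
# probability; returns the reference unchanged when jitter is 0
jitter_mask <- function(mask, jitter) {
  if (jitter == 0) return(mask)
  out <- shift_mask(mask, round(rnorm(1, 0, jitter)), round(rnorm(1, 0, jitter)))
  boundary <- which(boundary_pixels(out))
  if (length(boundary)) {
    p_flip <- min(0.5, jitter / 10)
    flip <- boundary[runif(length(boundary)) < p_flip]
    out[flip] <- 1 - out[flip]
  }
  if (sum(out) == 0) mask else out
}

# a grossly discordant reading: same lesion translated far across the frame
outlier_mask <- function(mask) {
  shifted <- shift_mask(mask, floor(nrow(mask) / 2), floor(ncol(mask) / 2))
  if (sum(shifted) == 0) {
    shifted <- matrix(0, nrow(mask), ncol(mask))
    shifted[1:2, 1:2] <- 1
  }
  shifted
}

shift_mask <- function(mask, di, dj) {
  out <- matrix(0, nrow(mask), ncol(mask))
  src <- which(mask == 1, arr.ind = TRUE)
  dst_i <- src[, 1] + di
  dst_j <- src[, 2] + dj
  ok <- dst_i >= 1 & dst_i <= nrow(mask) & dst_j >= 1 & dst_j <= ncol(mask)
  out[cbind(dst_i[ok], dst_j[ok])] <- 1
  out
}

# pixels whose 4-neighbourhood is not constant
boundary_pixels <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  up <- rbind(mask[1, , drop = FALSE], mask[-nr, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], mask[nr, , drop = FALSE])
  lf <- cbind(mask[, 1, drop = FALSE], mask[, -nc, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], mask[, nc, drop = FALSE])
  (mask != up) | (mask != dn) | (mask != lf) | (mask != rt)
}
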