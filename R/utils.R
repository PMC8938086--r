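# internal helpers shared across modules

clip255 <- function(x) pmin(pmax(x, 0), 255)

# round-half-up, matching how the reference tables print percentages
# (base round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_odd <- function(x) x %% 2 == 1

check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (anyNA(image) || any(image < 0) || any(image > 255)) {
    abort(sprintf("`%s` must have intensities in [0, 255] with no NA.", arg))
  }
  invisible(image)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (!all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (values 0/1).", arg))
  }
  invisible(mask)
}

check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("The two %s must have identical dimensions.", what))
  }
  invisible(NULL)
}

# deterministic child seeds so sub-generators can be re-run independently;
# kept below 2^31 - 1 so they remain valid R integers
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

check_prob <- function(p, arg) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", arg))
  }
  invisible(p)
}

check_count <- function(n, arg, min = 1) {
  if (length(n) != 1 || is.na(n) || n < min || n != as.integer(n)) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  invisible(as.integer(n))
}
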