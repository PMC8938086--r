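# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Brute-force adaptive median filter: literal per-pixel transcription of the
# two-level decision, using clamped-index windows (equivalent to edge
# replication) and an explicit sorted median.
oracle_amf <- function(img, init, smax) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      w <- init
      res <- NULL
      while (is.null(res)) {
        h <- (w - 1) / 2
        vals <- c()
        for (di in -h:h) {
          for (dj in -h:h) {
            ii <- min(max(i + di, 1), nr)
            jj <- min(max(j + dj, 1), nc)
            vals <- c(vals, img[ii, jj])
          }
        }
        s <- sort(vals)
        zmin <- s[1]
        zmax <- s[length(s)]
        zmed <- s[(length(s) + 1) / 2]
        zxy <- img[i, j]
        if (zmed > zmin && zmax > zmed) {
          res <- if (zxy > zmin && zmax > zxy) zxy else zmed
        } else if (w >= smax) {
          res <- zxy
        } else {
          w <- w + 2
        }
      }
      out[i, j] <- res
    }
  }
  out
}

# Naive trapezoid integration of a precision-recall point list.
oracle_trapezoid <- function(recall, precision) {
  area <- 0
  for (i in seq_len(length(recall) - 1)) {
    area <- area + (recall[i + 1] - recall[i]) *
      (precision[i] + precision[i + 1]) / 2
  }
  area
}

random_image <- function(nr, nc) {
  matrix(as.double(sample(0:255, nr * nc, replace = TRUE)), nr, nc)
}

random_mask <- function(nr = 12, nc = 12, p = 0.4) {
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

# random monotone PR curve with recall from 0 to 1
random_pr_curve <- function(n_points = 8) {
  recall <- sort(c(0, runif(n_points - 2), 1))
  precision <- runif(n_points)
  list(recall = recall, precision = precision)
}
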