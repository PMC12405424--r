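# Shared fixtures built in code.

# Deterministic random RGB image with values in [lo, hi].
random_image <- function(height, width, seed = 1L, lo = 0L, hi = 255L) {
  withr::with_seed(seed, {
    array(
      sample(lo:hi, height * width * 3L, replace = TRUE),
      dim = c(height, width, 3L)
    )
  })
}

constant_image <- function(height, width, value = 128L) {
  array(as.integer(value), dim = c(height, width, 3L))
}

# Published coefficient vector and the stages used throughout.
tab_coeffs <- published_coefficients()
podding <- stage_params(113, 27.0)
flowering <- stage_params(23, 30.4)

# Circular hue difference in degrees, in [0, 180].
hue_diff <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

# Least-squares slope of per-column mean brightness (all channels pooled).
column_mean_slope <- function(image) {
  means <- apply(image, 2L, mean)
  unname(stats::coef(stats::lm(means ~ seq_along(means)))[2L])
}

# Brute-force truncated+renormalized Gaussian convolution (square support of
# radius ceiling(3 sigma)), the oracle for the package's smoothing.
brute_gauss_smooth <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  n <- nrow(x)
  m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      wsum <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
            w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
            acc <- acc + w * x[ii, jj]
            wsum <- wsum + w
          }
        }
      }
      out[i, j] <- acc / wsum
    }
  }
  out
}
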