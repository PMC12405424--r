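# Baseline enhancers the compensation method is compared against:
# per-channel histogram equalization, multi-scale Retinex, gamma correction.

#' Multi-scale Retinex parameters
#'
#' @param sigmas Gaussian surround scales in pixels, at least one. Defaults
#'   `c(15, 80, 250)`, the conventional small/medium/large surround triple.
#' @param weights Nonnegative per-scale weights summing to one; default equal.
#' @param log_offset Positive constant added before logarithms (on the 0-255
#'   scale) to avoid log(0); default 1.
#' @return A list of class `msr_params`.
#' @export
msr_params <- function(sigmas = c(15, 80, 250),
                       weights = rep(1 / length(sigmas), length(sigmas)),
                       log_offset = 1) {
  if (!is.numeric(sigmas) || length(sigmas) < 1L ||
    !all(is.finite(sigmas)) || any(sigmas <= 0)) {
    stop_domain("`sigmas` must be one or more positive scales.")
  }
  if (!is.numeric(weights) || length(weights) != length(sigmas) ||
    any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_domain("`weights` must be nonnegative, one per scale, and sum to 1.")
  }
  check_number(log_offset, "log_offset", lower = 0, closed_lower = FALSE)
  structure(
    list(sigmas = sigmas, weights = weights, log_offset = log_offset),
    class = "msr_params"
  )
}

#' Gamma-correction parameters
#'
#' @param gamma Exponent of the power-law mapping (> 0). Values below one
#'   brighten dark regions; above one they suppress overexposed ones.
#'   Default 0.8, the brightening direction relevant for shaded canopies.
#' @param constant Multiplicative constant C (> 0), default 1.
#' @return A list of class `gamma_params`.
#' @export
gamma_params <- function(gamma = 0.8, constant = 1) {
  check_number(gamma, "gamma", lower = 0, closed_lower = FALSE)
  check_number(constant, "constant", lower = 0, closed_lower = FALSE)
  structure(list(gamma = gamma, constant = constant), class = "gamma_params")
}

#' Per-channel histogram equalization
#'
#' Each channel is independently remapped by the standard cumulative
#' distribution transform `T(v) = round(255 * (cdf(v) - cdf_min) / (1 - cdf_min))`,
#' spreading the grey levels across the dynamic range. A channel taking a
#' single value is left unchanged. Per-channel application matches the strong
#' colour shifts this method is known to produce on canopy imagery.
#'
#' @param image RGB image array (height x width x 3, integers 0-255).
#' @return Equalized image, same dimensions.
#' @export
equalize_hist <- function(image) {
  assert_rgb_image(image)
  out <- image
  n <- prod(dim(image)[1:2])
  for (ch in 1:3) {
    v <- as.integer(image[, , ch])
    counts <- tabulate(v + 1L, nbins = 256L)
    cdf <- cumsum(counts) / n
    cdf_min <- min(cdf[counts > 0])
    if (cdf_min >= 1) next # single grey level: identity
    map <- round_half_up(255 * (cdf - cdf_min) / (1 - cdf_min))
    out[, , ch] <- map[v + 1L]
  }
  storage.mode(out) <- "integer"
  out
}

#' Multi-scale Retinex enhancement
#'
#' Estimates the illumination component of each channel by Gaussian smoothing
#' at several spatial scales and recovers reflectance as the weighted
#' log-difference
#' `R = sum_i w_i * (log(I + eps) - log(G_sigma_i * I + eps))`,
#' where `G_sigma * I` is convolution with a normalized Gaussian truncated at
#' radius `ceiling(3 sigma)` and renormalized where the support is cut by the
#' image border. The reflectance field is then min-max rescaled per channel to
#' the display range \[0, 255\]; an all-equal field maps to 0.
#'
#' @param image RGB image array (height x width x 3, integers 0-255).
#' @param params An [msr_params()] object.
#' @return Enhanced image, same dimensions.
#' @export
msr_enhance <- function(image, params = msr_params()) {
  assert_rgb_image(image)
  if (!inherits(params, "msr_params")) {
    stop_domain("`params` must be an msr_params object.")
  }
  d <- dim(image)
  span <- max(gauss_kernel_span(max(params$sigmas)))
  if (span > d[1L] || span > d[2L]) {
    warning(sprintf(
      "largest Gaussian support (%d px) exceeds the image; kernel truncated and renormalized",
      span
    ), call. = FALSE)
  }
  eps <- params$log_offset
  out <- image
  for (ch in 1:3) {
    x <- image[, , ch, drop = TRUE] * 1.0
    logx <- log(x + eps)
    r <- matrix(0, d[1L], d[2L])
    for (k in seq_along(params$sigmas)) {
      blur <- gauss_smooth(x, params$sigmas[k])
      r <- r + params$weights[k] * (logx - log(blur + eps))
    }
    rng <- range(r)
    out[, , ch] <- if (rng[2L] - rng[1L] <= 1e-12) {
      matrix(0L, d[1L], d[2L])
    } else {
      round_half_up(255 * (r - rng[1L]) / (rng[2L] - rng[1L]))
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Gamma correction
#'
#' Power-law brightness remapping `v -> round(255 * C * (v/255)^gamma)`,
#' clipped to \[0, 255\].
#'
#' @param image RGB image array (height x width x 3, integers 0-255).
#' @param params A [gamma_params()] object.
#' @return Corrected image, same dimensions.
#' @examples
#' img <- array(64L, dim = c(2, 2, 3))
#' gamma_correct(img, gamma_params(gamma = 0.5))[1, 1, 1]
#' @export
gamma_correct <- function(image, params = gamma_params()) {
  assert_rgb_image(image)
  if (!inherits(params, "gamma_params")) {
    stop_domain("`params` must be a gamma_params object.")
  }
  out <- clip01(round_half_up(
    255 * params$constant * (image / 255)^params$gamma
  ))
  storage.mode(out) <- "integer"
  out
}
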