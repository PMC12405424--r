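# Internal helpers shared across modules.

# Classed conditions so that callers (and the CLI) can branch on error type.
cl_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("canopylight_", class), "canopylight_error"), ...)
}

stop_domain <- function(message, ...) cl_abort(message, "domain_error", ...)
stop_dimension <- function(message, ...) cl_abort(message, "dimension_error", ...)
stop_io <- function(message, ...) cl_abort(message, "io_error", ...)

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number.", arg))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_domain(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", arg,
      if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

deg2rad <- function(deg) deg * pi / 180

# Round half away from zero. Inputs here are nonnegative pixel values, for
# which this is floor(x + 0.5); kept explicit so the rule is platform-stable
# (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# --- image validation ---------------------------------------------------

# Images are plain numeric arrays, height x width x 3 (R, G, B), integer
# values in [0, 255]. Left edge is the sun-adjacent (shaded) side.
assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop_domain(sprintf("`%s` must be a height x width x 3 array.", arg))
  }
  d <- dim(image)
  if (d[1L] < 1L || d[2L] < 2L) {
    stop_domain(sprintf("`%s` must have height >= 1 and width >= 2.", arg))
  }
  if (anyNA(image) || !is.numeric(image)) {
    stop_domain(sprintf("`%s` contains missing or non-numeric values.", arg))
  }
  rng <- range(image)
  if (rng[1L] < 0 || rng[2L] > 255) {
    stop_domain(sprintf("`%s` has pixel values outside [0, 255].", arg))
  }
  if (max(abs(image - round(image))) > 1e-8) {
    stop_domain(sprintf("`%s` must hold integer pixel values.", arg))
  }
  invisible(image)
}

assert_same_dims <- function(a, b, arg_a = "image_a", arg_b = "image_b") {
  if (!identical(dim(a), dim(b))) {
    stop_dimension(sprintf(
      "`%s` (%s) and `%s` (%s) must have identical dimensions.",
      arg_a, paste(dim(a), collapse = "x"), arg_b, paste(dim(b), collapse = "x")
    ))
  }
  invisible(TRUE)
}

# --- Gaussian smoothing -------------------------------------------------

# One-dimensional truncated-Gaussian smoothing matrix: entry (i, j) holds the
# kernel weight exp(-(i-j)^2 / (2 sigma^2)) for |i - j| <= radius, rows
# renormalized to sum to one. Applying it along rows and columns is exactly
# the separable 2-D convolution with a truncated, boundary-renormalized
# Gaussian (the in-bounds weight sum over a rectangle factorizes).
gauss_weight_matrix <- function(n, sigma) {
  radius <- ceiling(3 * sigma)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- exp(-(d^2) / (2 * sigma^2))
  w[d > radius] <- 0
  w / rowSums(w)
}

# 2-D Gaussian smoothing of a numeric matrix with the boundary rule above.
gauss_smooth <- function(x, sigma) {
  wr <- gauss_weight_matrix(nrow(x), sigma)
  wc <- gauss_weight_matrix(ncol(x), sigma)
  wr %*% x %*% t(wc)
}

gauss_kernel_span <- function(sigma) 2L * ceiling(3 * sigma) + 1L
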