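# Evaluation stack: MSE/PSNR, RGB and HLS centerline profiles, trimmed
# per-channel standard deviations.

#' Mean squared error between two images
#'
#' Mean over all pixels and all three channels of the squared differences,
#' computed in double precision (no 8-bit overflow).
#'
#' @param image_a,image_b RGB image arrays with identical dimensions.
#' @return Scalar MSE in squared intensity units.
#' @examples
#' a <- array(0L, c(4, 4, 3)); b <- array(16L, c(4, 4, 3))
#' mse_image(a, b) # 256
#' @export
mse_image <- function(image_a, image_b) {
  assert_rgb_image(image_a, "image_a")
  assert_rgb_image(image_b, "image_b")
  assert_same_dims(image_a, image_b)
  mean((as.numeric(image_a) - as.numeric(image_b))^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(max_value^2 / MSE)`, in decibels. Identical images have
#' zero MSE; the documented sentinel for that case is `Inf`.
#'
#' @inheritParams mse_image
#' @param max_value Peak representable intensity, default 255.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(image_a, image_b, max_value = 255) {
  check_number(max_value, "max_value", lower = 0, closed_lower = FALSE)
  m <- mse_image(image_a, image_b)
  if (m == 0) {
    return(Inf)
  }
  10 * log10(max_value^2 / m)
}

# --- HLS (hexcone) colour model ------------------------------------------

#' Convert between RGB and HLS
#'
#' Standard hexcone (double-cone) model. Hue is in degrees in \[0, 360) with
#' the undefined hue of achromatic pixels reported as 0; lightness and
#' saturation are rescaled to \[0, 255\] to share axes with the RGB channels.
#' Inputs and outputs are vectorized.
#'
#' @param r,g,b Channel values in \[0, 255\].
#' @return `rgb_to_hls()`: a list with numeric vectors `h`, `l`, `s`.
#' @examples
#' rgb_to_hls(255, 0, 0) # h = 0, l = 127.5, s = 255
#' @export
rgb_to_hls <- function(r, g, b) {
  rp <- r / 255; gp <- g / 255; bp <- b / 255
  maxc <- pmax(rp, gp, bp)
  minc <- pmin(rp, gp, bp)
  delta <- maxc - minc
  l <- (maxc + minc) / 2
  s <- ifelse(delta == 0, 0,
    ifelse(l <= 0.5, delta / (maxc + minc), delta / (2 - maxc - minc))
  )
  h <- numeric(length(l))
  nz <- delta > 0
  hr <- nz & maxc == rp
  hg <- nz & !hr & maxc == gp
  hb <- nz & !hr & !hg
  h[hr] <- 60 * (((gp[hr] - bp[hr]) / delta[hr]) %% 6)
  h[hg] <- 60 * ((bp[hg] - rp[hg]) / delta[hg] + 2)
  h[hb] <- 60 * ((rp[hb] - gp[hb]) / delta[hb] + 4)
  h <- h %% 360
  list(h = h, l = 255 * l, s = 255 * s)
}

#' @rdname rgb_to_hls
#' @param h Hue in degrees, \[0, 360).
#' @param l,s Lightness and saturation in \[0, 255\].
#' @return `hls_to_rgb()`: a list with numeric vectors `r`, `g`, `b` in
#'   \[0, 255\] (not rounded).
#' @export
hls_to_rgb <- function(h, l, s) {
  lp <- l / 255; sp <- s / 255
  c <- (1 - abs(2 * lp - 1)) * sp
  hp <- (h %% 360) / 60
  x <- c * (1 - abs(hp %% 2 - 1))
  m <- lp - c / 2
  sext <- pmin(floor(hp), 5)
  r1 <- ifelse(sext == 0 | sext == 5, c, ifelse(sext == 1 | sext == 4, x, 0))
  g1 <- ifelse(sext == 1 | sext == 2, c, ifelse(sext == 0 | sext == 3, x, 0))
  b1 <- ifelse(sext == 3 | sext == 4, c, ifelse(sext == 2 | sext == 5, x, 0))
  list(r = 255 * (r1 + m), g = 255 * (g1 + m), b = 255 * (b1 + m))
}

image_hls <- function(image) {
  rgb_to_hls(
    as.numeric(image[, , 1L]),
    as.numeric(image[, , 2L]),
    as.numeric(image[, , 3L])
  )
}

# Centered moving average with edge truncation (mean over in-bounds window).
moving_average <- function(x, window) {
  if (window == 1L) {
    return(x)
  }
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Channel profile along the horizontal centerline
#'
#' Samples channel values along the row at index `floor(height / 2)`
#' (0-based), left (shaded, south) to right (bright, north), optionally
#' smoothed by a centered moving average with edge truncation.
#'
#' @param image RGB image array (height x width x 3, integers 0-255).
#' @param colorspace `"rgb"` or `"hls"`.
#' @param smoothing_window Odd window width in columns, 1 = no smoothing.
#' @return A tibble with `column` plus channel columns (`r`, `g`, `b` or
#'   `h`, `l`, `s`).
#' @export
centerline_profile <- function(image, colorspace = c("rgb", "hls"),
                               smoothing_window = 1L) {
  assert_rgb_image(image)
  colorspace <- match.arg(colorspace)
  w <- dim(image)[2L]
  if (!is.numeric(smoothing_window) || length(smoothing_window) != 1L ||
    smoothing_window != round(smoothing_window) || smoothing_window < 1 ||
    smoothing_window %% 2 == 0 || smoothing_window > w) {
    stop_domain("`smoothing_window` must be an odd integer in [1, width].")
  }
  mid <- floor(dim(image)[1L] / 2) + 1L
  r <- as.numeric(image[mid, , 1L])
  g <- as.numeric(image[mid, , 2L])
  b <- as.numeric(image[mid, , 3L])
  prof <- if (colorspace == "rgb") {
    tibble::tibble(column = seq_len(w), r = r, g = g, b = b)
  } else {
    hls <- rgb_to_hls(r, g, b)
    tibble::tibble(column = seq_len(w), h = hls$h, l = hls$l, s = hls$s)
  }
  for (col in setdiff(names(prof), "column")) {
    prof[[col]] <- moving_average(prof[[col]], as.integer(smoothing_window))
  }
  prof
}

#' Per-channel standard deviation over the central columns
#'
#' Drops the leftmost and rightmost `floor(width / 10)` columns — the strip
#' boundaries, where channel values change abruptly — and computes the
#' population standard deviation of each RGB channel and each HLS channel over
#' all remaining pixels.
#'
#' @param image RGB image array with width >= 10.
#' @return A tibble with columns `channel` (`R`, `G`, `B`, `H`, `L`, `S`) and
#'   `std`.
#' @export
trimmed_channel_std <- function(image) {
  assert_rgb_image(image)
  w <- dim(image)[2L]
  if (w < 10L) {
    stop_domain(sprintf("image width must be >= 10 columns (got %d).", w))
  }
  k <- floor(w / 10)
  kept <- image[, (k + 1L):(w - k), , drop = FALSE]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  hls <- image_hls(kept)
  tibble::tibble(
    channel = c("R", "G", "B", "H", "L", "S"),
    std = c(
      pop_sd(as.numeric(kept[, , 1L])),
      pop_sd(as.numeric(kept[, , 2L])),
      pop_sd(as.numeric(kept[, , 3L])),
      pop_sd(hls$h), pop_sd(hls$l), pop_sd(hls$s)
    )
  )
}

#' Full evaluation report for an enhanced image
#'
#' Computes the quantitative and qualitative evaluation protocol in one call:
#' MSE and PSNR of the processed image against the original (and, when a
#' uniformly lit ground truth exists, against it as well — the meaningful
#' pairing for synthetic scenes), the six trimmed per-channel standard
#' deviations of the processed image, and its RGB and HLS centerline profiles.
#'
#' @param processed Enhanced RGB image array.
#' @param original The image before enhancement (same dimensions).
#' @param ground_truth Optional uniformly lit reference (same dimensions).
#' @param smoothing_window Passed to [centerline_profile()].
#' @return An object of class `enhancement_report`: list with `mse`, `psnr_db`,
#'   `mse_truth`, `psnr_truth_db` (NA when no ground truth), `channel_std`
#'   (tibble) and `profiles` (list of tibbles `rgb`, `hls`).
#' @export
evaluate_enhancement <- function(processed, original, ground_truth = NULL,
                                 smoothing_window = 1L) {
  m <- mse_image(processed, original)
  p <- psnr(processed, original)
  if (!is.null(ground_truth)) {
    mt <- mse_image(processed, ground_truth)
    pt <- psnr(processed, ground_truth)
  } else {
    mt <- NA_real_
    pt <- NA_real_
  }
  structure(
    list(
      mse = m, psnr_db = p, mse_truth = mt, psnr_truth_db = pt,
      channel_std = trimmed_channel_std(processed),
      profiles = list(
        rgb = centerline_profile(processed, "rgb", smoothing_window),
        hls = centerline_profile(processed, "hls", smoothing_window)
      )
    ),
    class = "enhancement_report"
  )
}

#' @export
print.enhancement_report <- function(x, ...) {
  cat(sprintf(
    "<enhancement_report> MSE %.4g, PSNR %s dB vs original",
    x$mse, if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.2f", x$psnr_db)
  ))
  if (!is.na(x$psnr_truth_db)) {
    cat(sprintf(
      "; PSNR %s dB vs ground truth",
      if (is.infinite(x$psnr_truth_db)) "Inf" else sprintf("%.2f", x$psnr_truth_db)
    ))
  }
  cat("\n")
  print(tidyr::pivot_wider(x$channel_std, names_from = "channel", values_from = "std"))
  invisible(x)
}

#' @export
glance.enhancement_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$channel_std,
    names_from = "channel", values_from = "std", names_prefix = "std_"
  )
  dplyr::bind_cols(
    tibble::tibble(
      mse = x$mse, psnr_db = x$psnr_db,
      mse_truth = x$mse_truth, psnr_truth_db = x$psnr_truth_db
    ),
    wide
  )
}

#' @export
autoplot.enhancement_report <- function(object, colorspace = c("rgb", "hls"), ...) {
  colorspace <- match.arg(colorspace)
  prof <- object$profiles[[colorspace]]
  long <- tidyr::pivot_longer(prof, -"column",
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$column, .data$value,
    colour = .data$channel
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "image column (shaded → bright)", y = "channel value",
      title = sprintf("%s centerline profile", toupper(colorspace))
    )
}
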