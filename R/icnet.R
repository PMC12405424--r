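#' Map image columns to positions within the shaded strip
#'
#' Linearly spaces the strip position coordinate l across the pixel columns,
#' from `l_min` at the left (sun-adjacent, shaded) edge to `l_max` at the
#' right edge. The defaults span the six measured row positions, 30-180 cm.
#'
#' @param width Number of image columns (>= 2).
#' @param l_min,l_max Positions (cm) assigned to the first and last column.
#' @return Numeric vector of length `width`, strictly increasing.
#' @examples
#' column_positions(6) # 30 60 90 120 150 180
#' @export
column_positions <- function(width, l_min = 30, l_max = 180) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
    width != round(width) || width < 2) {
    stop_domain("`width` must be a single integer >= 2.")
  }
  check_number(l_min, "l_min")
  check_number(l_max, "l_max")
  if (l_min >= l_max) stop_domain("`l_min` must be strictly less than `l_max`.")
  seq(l_min, l_max, length.out = width)
}

#' Clamped per-column brightness adjustment ratios
#'
#' For each column the adjustment ratio is the reference intensity divided by
#' the column's target (model-predicted) intensity, constrained to the range
#' `[clamp_lo, clamp_hi]` (default 0.5-1.2) to prevent excessive enhancement
#' or reduction. Columns predicted dimmer than the reference get ratios above
#' one and are brightened.
#'
#' @param targets Per-column predicted intensities (all > 0).
#' @param reference Scalar reference intensity (> 0).
#' @param clamp_lo,clamp_hi Clamp bounds, `clamp_lo < clamp_hi`.
#' @return Numeric vector of ratios, same length as `targets`, all within
#'   the clamp bounds.
#' @examples
#' compute_ratios(c(50, 100, 2000), reference = 100)
#' @export
compute_ratios <- function(targets, reference, clamp_lo = 0.5, clamp_hi = 1.2) {
  if (!is.numeric(targets) || length(targets) < 1L || !all(is.finite(targets))) {
    stop_domain("`targets` must be a nonempty finite numeric vector.")
  }
  if (any(targets <= 0)) {
    stop_domain("`targets` must be strictly positive.")
  }
  check_number(reference, "reference", lower = 0, closed_lower = FALSE)
  check_number(clamp_lo, "clamp_lo", lower = 0, closed_lower = FALSE)
  check_number(clamp_hi, "clamp_hi", lower = 0, closed_lower = FALSE)
  if (clamp_lo >= clamp_hi) stop_domain("`clamp_lo` must be less than `clamp_hi`.")
  pmin(pmax(reference / targets, clamp_lo), clamp_hi)
}

#' Scale image columns by per-column ratios
#'
#' Multiplies every pixel of column c, identically on the three channels, by
#' `ratios[c]`, rounds half away from zero and clips to the display range
#' \[0, 255\]. Columns with ratio exactly 1 are bit-identical to the input.
#'
#' @param image RGB image array (height x width x 3, integers 0-255).
#' @param ratios Positive numeric vector, one entry per image column.
#' @return The compensated image, same dimensions and storage as `image`.
#' @export
apply_compensation <- function(image, ratios) {
  assert_rgb_image(image)
  w <- dim(image)[2L]
  if (!is.numeric(ratios) || length(ratios) != w) {
    stop_dimension(sprintf(
      "`ratios` has length %d but the image has %d columns.", length(ratios), w
    ))
  }
  if (!all(is.finite(ratios)) || any(ratios <= 0)) {
    stop_domain("`ratios` must all be positive and finite.")
  }
  out <- image
  for (ch in 1:3) {
    scaled <- sweep(image[, , ch, drop = TRUE], 2L, ratios, "*")
    out[, , ch] <- clip01(round_half_up(scaled))
  }
  storage.mode(out) <- "integer"
  out
}

#' Column-wise model-driven illumination compensation (ICNet)
#'
#' The full compensation pipeline: image columns are mapped to strip positions
#' ([column_positions()]), the quadratic model predicts a target intensity per
#' column ([predict_intensity()]), clamped adjustment ratios are formed against
#' a reference intensity ([compute_ratios()]) and applied column-by-column
#' ([apply_compensation()]). The enhanced image plus the complete per-column
#' profile are returned for audit.
#'
#' The reference intensity is, by default, the predicted intensity of the
#' brightest column (`"brightest"`), so the shaded side is brightened toward
#' the sunlit side and, up to the upper clamp, all ratios are >= 1.
#' Alternatives: `"mean"` (mean predicted intensity) or `"fixed"` (caller
#' supplies `reference_value`).
#'
#' The quadratic model can extrapolate below zero at the most-shaded edge for
#' large height differences. Such nonpositive targets are floored at a tiny
#' positive fraction of the reference before ratio formation, so the affected
#' columns saturate at the upper clamp — the maximal admissible brightening.
#' The raw (unfloored) predictions are kept in the returned profile.
#'
#' @inheritParams compute_ratios
#' @param image RGB image array (height x width x 3, integers 0-255), left
#'   edge = shaded side.
#' @param coeffs A [poly_coefficients()] vector.
#' @param stage A [stage_params()] object.
#' @param reference_policy `"brightest"`, `"mean"` or `"fixed"`.
#' @param reference_value Reference intensity when `reference_policy` is
#'   `"fixed"`.
#' @param l_range Strip positions assigned to the first and last column,
#'   default `c(30, 180)` cm.
#' @return An object of class `icnet_result`: list with `image` (enhanced
#'   array) and `profile`, a tibble with one row per column: `column`,
#'   `position_cm`, `target` (raw prediction), `reference`, `ratio`.
#' @examples
#' scn <- generate_canopy_image(scene_spec(64, 48, stage_params(23, 30.4)))
#' res <- icnet_enhance(scn$shaded, published_coefficients(), stage_params(23, 30.4))
#' head(tidy(res))
#' @export
icnet_enhance <- function(image, coeffs, stage,
                          reference_policy = c("brightest", "mean", "fixed"),
                          reference_value = NULL,
                          clamp_lo = 0.5, clamp_hi = 1.2,
                          l_range = c(30, 180)) {
  assert_rgb_image(image)
  reference_policy <- match.arg(reference_policy)
  if (!inherits(stage, "stage_params")) {
    stop_domain("`stage` must be a stage_params object.")
  }
  w <- dim(image)[2L]
  positions <- column_positions(w, l_range[1L], l_range[2L])
  targets <- predict_intensity(
    coeffs, stage$height_difference_cm, stage$solar_elevation_deg, positions,
    calibrated_range = l_range
  )
  reference <- switch(reference_policy,
    brightest = max(targets),
    mean = mean(targets),
    fixed = {
      if (is.null(reference_value)) {
        stop_domain("`reference_value` is required when reference_policy = \"fixed\".")
      }
      reference_value
    }
  )
  if (!is.finite(reference) || reference <= 0) {
    stop_domain(sprintf(
      "reference intensity must be positive (policy '%s' gave %g).",
      reference_policy, reference
    ))
  }
  floored <- pmax(targets, reference * .Machine$double.eps)
  ratios <- compute_ratios(floored, reference, clamp_lo, clamp_hi)
  structure(
    list(
      image = apply_compensation(image, ratios),
      profile = tibble::tibble(
        column = seq_len(w),
        position_cm = positions,
        target = targets,
        reference = reference,
        ratio = ratios
      ),
      reference_policy = reference_policy
    ),
    class = "icnet_result"
  )
}

#' @export
print.icnet_result <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<icnet_result> %dx%d image, reference %.6g (%s policy), ratios in [%.3f, %.3f]\n",
    d[1L], d[2L], x$profile$reference[1L], x$reference_policy,
    min(x$profile$ratio), max(x$profile$ratio)
  ))
  invisible(x)
}

#' @export
tidy.icnet_result <- function(x, ...) x$profile

#' @export
autoplot.icnet_result <- function(object, ...) {
  prof <- object$profile
  long <- tidyr::pivot_longer(
    dplyr::mutate(prof, target_rel = .data$target / .data$reference),
    c("ratio", "target_rel"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$position_cm, .data$value,
    colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "strip position l (cm)", y = "value",
      title = "Column-wise compensation profile",
      colour = NULL
    ) +
    ggplot2::scale_colour_discrete(
      labels = c(ratio = "adjustment ratio", target_rel = "target / reference")
    )
}
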