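# Seeded generators standing in for undeposited field data: canopy-like
# scenes with model-driven shading plus uniformly lit ground truth, and noisy
# light-intensity measurement tables for regression tests.

#' Specification of a synthetic canopy scene
#'
#' Describes a green-dominant canopy texture (the uniformly lit ground truth)
#' and the multiplicative left-to-right shading field derived from the
#' quadratic illumination model. Shading is multiplicative on reflectance
#' (image = texture x illumination), matching the Retinex image-formation
#' model; the model prediction is affinely rescaled so the brightest column
#' maps to 1 and the darkest to `shade_floor` (absolute instrument units
#' cannot map to 8-bit pixels without an unknown camera response).
#'
#' @param width,height Image size in pixels.
#' @param stage A [stage_params()] object (default: the podding stage,
#'   h = 113 cm, theta = 27 degrees, where shading is strongest).
#' @param coeffs A [poly_coefficients()] vector (default:
#'   [published_coefficients()]).
#' @param texture_seed Integer seed for the texture and pixel noise.
#' @param shade_floor Multiplicative shading of the darkest column, in (0, 1];
#'   default 0.6.
#' @param noise_sd Gaussian pixel-noise standard deviation added to the shaded
#'   image (intensity units), default 0.
#' @param channel_means Mean (R, G, B) of the unshaded texture; default
#'   `c(140, 190, 120)`, a green-dominant canopy.
#' @param l_range Strip positions spanned by the columns, default
#'   `c(30, 180)` cm.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width, height,
                       stage = stage_params(113, 27.0),
                       coeffs = published_coefficients(),
                       texture_seed = 1L,
                       shade_floor = 0.6,
                       noise_sd = 0,
                       channel_means = c(140, 190, 120),
                       l_range = c(30, 180)) {
  if (!is.numeric(width) || width < 2 || width != round(width)) {
    stop_domain("`width` must be an integer >= 2.")
  }
  if (!is.numeric(height) || height < 1 || height != round(height)) {
    stop_domain("`height` must be an integer >= 1.")
  }
  if (!inherits(stage, "stage_params")) {
    stop_domain("`stage` must be a stage_params object.")
  }
  if (!inherits(coeffs, "poly_coefficients")) {
    stop_domain("`coeffs` must be a poly_coefficients object.")
  }
  check_number(shade_floor, "shade_floor", lower = 0, upper = 1, closed_lower = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(texture_seed, "texture_seed")
  if (!is.numeric(channel_means) || length(channel_means) != 3L ||
    any(channel_means < 0 | channel_means > 255)) {
    stop_domain("`channel_means` must be three values in [0, 255].")
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      stage = stage, coeffs = coeffs,
      texture_seed = as.integer(texture_seed),
      shade_floor = shade_floor, noise_sd = noise_sd,
      channel_means = channel_means, l_range = l_range
    ),
    class = "scene_spec"
  )
}

# Smoothed-noise layer: white noise blurred at `sigma`, standardized and
# scaled to the requested standard deviation.
texture_layer <- function(height, width, sigma, sd_out) {
  x <- gauss_smooth(matrix(stats::rnorm(height * width), height, width), sigma)
  x <- x - mean(x)
  s <- stats::sd(as.numeric(x))
  if (s < .Machine$double.eps) {
    return(matrix(0, height, width))
  }
  x * (sd_out / s)
}

#' Generate a synthetic shaded canopy scene
#'
#' Builds a seeded, green-dominant canopy texture (sum of a coarse canopy
#' layer and a fine leaf-speckle layer of smoothed noise, shared across
#' channels so leaf structure is colour-coherent) as the uniformly lit ground
#' truth; derives a per-column shading field from the quadratic illumination
#' model rescaled to `[shade_floor, 1]`; and returns the shaded image
#' `round(ground_truth * shading)` (plus optional Gaussian pixel noise),
#' clipped to \[0, 255\]. Ground truth, shaded image and the shading field are
#' all returned so that enhancement can be scored against truth.
#'
#' Identical specs (including `texture_seed`) produce bit-identical scenes.
#'
#' @param spec A [scene_spec()] object.
#' @return A list of class `canopy_scene`: `shaded` and `ground_truth` (RGB
#'   image arrays), `shading_field` (per-column factors, attribute `monotone`
#'   records whether it is nondecreasing left to right), `positions_cm`, and
#'   the `spec`.
#' @examples
#' scn <- generate_canopy_image(scene_spec(64, 48, texture_seed = 7))
#' range(scn$shading_field)
#' @export
generate_canopy_image <- function(spec) {
  if (!inherits(spec, "scene_spec")) {
    stop_domain("`spec` must be a scene_spec object.")
  }
  h <- spec$height
  w <- spec$width
  positions <- column_positions(w, spec$l_range[1L], spec$l_range[2L])
  pred <- predict_intensity(
    spec$coeffs, spec$stage$height_difference_cm,
    spec$stage$solar_elevation_deg, positions,
    calibrated_range = spec$l_range
  )
  rng <- range(pred)
  field <- if (rng[2L] - rng[1L] <= .Machine$double.eps * max(1, abs(rng[2L]))) {
    rep(1, w) # column-constant prediction: no shading gradient
  } else {
    spec$shade_floor + (1 - spec$shade_floor) * (pred - rng[1L]) / (rng[2L] - rng[1L])
  }
  attr(field, "monotone") <- all(diff(field) >= 0)

  scene <- with_local_seed(spec$texture_seed, {
    coarse <- texture_layer(h, w, sigma = max(3, min(h, w) / 12), sd_out = 22)
    fine <- texture_layer(h, w, sigma = 1.2, sd_out = 8)
    base <- coarse + fine
    gt <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) {
      gt[, , ch] <- clip01(round_half_up(spec$channel_means[ch] + base))
    }
    storage.mode(gt) <- "integer"
    shaded <- gt
    for (ch in 1:3) {
      x <- sweep(gt[, , ch, drop = TRUE] * 1.0, 2L, field, "*")
      if (spec$noise_sd > 0) {
        x <- x + stats::rnorm(length(x), sd = spec$noise_sd)
      }
      shaded[, , ch] <- clip01(round_half_up(pmax(x, 0)))
    }
    storage.mode(shaded) <- "integer"
    list(gt = gt, shaded = shaded)
  })

  structure(
    list(
      shaded = scene$shaded,
      ground_truth = scene$gt,
      shading_field = field,
      positions_cm = positions,
      spec = spec
    ),
    class = "canopy_scene"
  )
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf(
    "<canopy_scene> %dx%d, shading %.3f..%.3f (%s), seed %d\n",
    x$spec$height, x$spec$width, min(x$shading_field), max(x$shading_field),
    if (isTRUE(attr(x$shading_field, "monotone"))) "monotone" else "non-monotone",
    x$spec$texture_seed
  ))
  invisible(x)
}

#' Generate noisy light-intensity measurement tables
#'
#' Emulates the field protocol of reading an illuminometer at fixed row
#' positions across growth stages: for every stage x position x replicate,
#' the intensity is the quadratic model prediction plus i.i.d. Gaussian noise.
#' With `noise_sd = 0` the samples satisfy the model exactly; identical seeds
#' give identical tables.
#'
#' @param coeffs A [poly_coefficients()] vector.
#' @param stages A data frame with columns `h_cm` and `theta_deg` (e.g.
#'   [growth_stages()]), or a list of [stage_params()] objects.
#' @param positions_cm Measurement positions within the strip, default
#'   `seq(30, 180, by = 30)` (the six instrumented rows).
#' @param noise_sd Gaussian measurement noise sd, intensity units; default 0.
#' @param n_reps Replicates per stage x position, >= 1.
#' @param seed Integer seed.
#' @return A tibble with columns `h_cm`, `theta_deg`, `l_cm`, `rep`,
#'   `intensity`.
#' @export
generate_measurements <- function(coeffs, stages,
                                  positions_cm = seq(30, 180, by = 30),
                                  noise_sd = 0, n_reps = 1L, seed = 1L) {
  if (!inherits(coeffs, "poly_coefficients")) {
    stop_domain("`coeffs` must be a poly_coefficients object.")
  }
  if (inherits(stages, "stage_params")) {
    stages <- list(stages)
  }
  if (is.list(stages) && !is.data.frame(stages)) {
    if (length(stages) == 0L) stop_domain("`stages` must not be empty.")
    stages <- dplyr::bind_rows(lapply(stages, as_stage_row))
  }
  stages <- as.data.frame(stages)
  if (nrow(stages) == 0L) stop_domain("`stages` must not be empty.")
  if (!all(c("h_cm", "theta_deg") %in% names(stages))) {
    stop_domain("`stages` must have columns h_cm and theta_deg.")
  }
  if (length(positions_cm) == 0L || any(positions_cm <= 0)) {
    stop_domain("`positions_cm` must be a nonempty vector of positive positions.")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
    stop_domain("`n_reps` must be an integer >= 1.")
  }
  grid <- tidyr::expand_grid(
    stage_idx = seq_len(nrow(stages)),
    l_cm = positions_cm,
    rep = seq_len(n_reps)
  )
  h <- stages$h_cm[grid$stage_idx]
  th <- stages$theta_deg[grid$stage_idx]
  mu <- predict_intensity(coeffs, h, th, grid$l_cm,
    calibrated_range = range(positions_cm)
  )
  y <- with_local_seed(seed, {
    mu + if (noise_sd > 0) stats::rnorm(length(mu), sd = noise_sd) else 0
  })
  tibble::tibble(
    h_cm = h, theta_deg = th, l_cm = grid$l_cm,
    rep = as.integer(grid$rep), intensity = y
  )
}
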