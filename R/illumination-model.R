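#' Direct illuminance under a given solar elevation
#'
#' Direct component of the light reaching the canopy, `E = E0 * cos(theta)`,
#' with theta the solar elevation angle in degrees. (The cosine convention is
#' kept exactly as the field model states it.)
#'
#' @param E0 Direct solar intensity (> 0), instrument units.
#' @param theta_deg Solar elevation angle in degrees, in \[0, 90).
#' @return Illuminance in the units of `E0`.
#' @examples
#' direct_illuminance(1000, 60) # 500
#' @export
direct_illuminance <- function(E0, theta_deg) {
  check_number(E0, "E0", lower = 0, closed_lower = FALSE)
  check_number(theta_deg, "theta_deg", lower = 0, upper = 90, closed_upper = FALSE)
  E0 * cos(deg2rad(theta_deg))
}

#' Shadow length cast by the taller crop strip
#'
#' Two conventions are provided. `"as-written"` (default) follows the field
#' model's printed form `L = h * tan(theta)`; `"geometric"` is the standard
#' shadow-geometry form `L = h / tan(theta)`. The two multiply to `h^2` for any
#' elevation angle, which is used as a cross-check in the tests.
#'
#' @param h_cm Canopy height difference in cm (>= 0).
#' @param theta_deg Solar elevation angle in degrees, strictly in (0, 90).
#' @param mode `"as-written"` or `"geometric"`.
#' @return Shadow length in cm.
#' @examples
#' shadow_length(100, 45) # 100 under either convention
#' @export
shadow_length <- function(h_cm, theta_deg, mode = c("as-written", "geometric")) {
  mode <- match.arg(mode)
  check_number(h_cm, "h_cm", lower = 0)
  check_number(theta_deg, "theta_deg",
    lower = 0, upper = 90, closed_lower = FALSE, closed_upper = FALSE
  )
  t <- tan(deg2rad(theta_deg))
  switch(mode, "as-written" = h_cm * t, geometric = h_cm / t)
}

#' Total illuminance in the shaded region
#'
#' Combines the direct term attenuated by a shading effect `f` with the
#' diffuse-sky and adjacent-strip reflection terms:
#' `E_shadow = E0 * (cos(theta) - f) + E0 * Df + E0 * alpha`.
#'
#' The shading effect `f(h, d)` has no closed form in the underlying model; the
#' caller supplies its value directly (default 0, i.e. no obstruction). In the
#' full pipeline the fitted polynomial model supersedes this physical sketch.
#'
#' @param stage A [stage_params()] object.
#' @param f_value Value of the shading-effect term, finite, default 0.
#' @return Illuminance in the units of the stage's `direct_solar_intensity`.
#' @examples
#' shadow_illuminance(stage_params(113, 27.0), f_value = 0.2)
#' @export
shadow_illuminance <- function(stage, f_value = 0) {
  if (!inherits(stage, "stage_params")) {
    stop_domain("`stage` must be a stage_params object.")
  }
  check_number(f_value, "f_value")
  E0 <- stage$direct_solar_intensity
  E0 * (cos(deg2rad(stage$solar_elevation_deg)) - f_value) +
    E0 * stage$diffuse_coefficient +
    E0 * stage$reflectance
}

# Design-matrix row block for the ten-term quadratic model; h, theta, l are
# recycled to a common length.
poly_design <- function(h_cm, theta_deg, l_cm) {
  n <- max(length(h_cm), length(theta_deg), length(l_cm))
  h <- rep_len(h_cm, n)
  th <- rep_len(theta_deg, n)
  l <- rep_len(l_cm, n)
  x <- cbind(
    1, h, th, l, h^2, h * th, th * l, th^2, h * l, l^2
  )
  colnames(x) <- poly_term_names
  x
}

#' Predict canopy light intensity from the quadratic model
#'
#' Evaluates the ten-term quadratic in (h, theta, l); see
#' [poly_coefficients()] for the model. theta is in degrees, matching the
#' units the published coefficients were fitted with. Vectorized over `l_cm`
#' (and over `h_cm`/`theta_deg` by recycling).
#'
#' @param coeffs A `poly_coefficients` vector.
#' @param h_cm Height difference in cm.
#' @param theta_deg Solar elevation angle in degrees.
#' @param l_cm Position(s) within the shaded strip, cm. Values outside
#'   `calibrated_range` trigger an extrapolation warning.
#' @param calibrated_range Range of l over which the model was calibrated,
#'   default `c(30, 180)` cm (the measured row positions).
#' @return Predicted light intensity, instrument units (same length as `l_cm`).
#' @examples
#' predict_intensity(published_coefficients(), 113, 27.0, seq(30, 180, 30))
#' @export
predict_intensity <- function(coeffs, h_cm, theta_deg, l_cm,
                              calibrated_range = c(30, 180)) {
  if (!inherits(coeffs, "poly_coefficients")) {
    stop_domain("`coeffs` must be a poly_coefficients object.")
  }
  if (!is.numeric(h_cm) || !is.numeric(theta_deg) || !is.numeric(l_cm) ||
    !all(is.finite(c(h_cm, theta_deg, l_cm)))) {
    stop_domain("`h_cm`, `theta_deg` and `l_cm` must be finite numerics.")
  }
  if (any(l_cm < calibrated_range[1L] | l_cm > calibrated_range[2L])) {
    warning(sprintf(
      "predicting outside the calibrated position range [%g, %g] cm",
      calibrated_range[1L], calibrated_range[2L]
    ), call. = FALSE)
  }
  drop(poly_design(h_cm, theta_deg, l_cm) %*% unclass(coeffs))
}

#' Fit the quadratic illumination model by ordinary least squares
#'
#' Fits the ten-term quadratic in (h, theta, l) to measured light-intensity
#' samples via a rank-revealing QR decomposition of the design matrix. A
#' rank-deficient design is an error that names the deficient columns rather
#' than a silent pseudo-inverse, because a degenerate fit would corrupt every
#' downstream compensation.
#'
#' @param samples A data frame with columns `h_cm`, `theta_deg`, `l_cm`,
#'   `intensity`; at least ten rows (the number of free parameters).
#' @return An object of class `light_fit` with elements `coefficients`
#'   (a [poly_coefficients()] vector), `r_squared`, `residual_sd`, `n_samples`,
#'   `fitted` and `residuals`. [tidy()] and [glance()] methods are provided.
#' @examples
#' tbl <- generate_measurements(published_coefficients(), calibration_grid())
#' fit <- fit_light_model(tbl)
#' glance(fit)
#' @export
fit_light_model <- function(samples) {
  samples <- as.data.frame(samples)
  needed <- c("h_cm", "theta_deg", "l_cm", "intensity")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols) > 0L) {
    stop_domain(sprintf(
      "`samples` lacks column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!all(is.finite(as.matrix(samples[needed])))) {
    stop_domain("`samples` contains non-finite values.")
  }
  n <- nrow(samples)
  x <- poly_design(samples$h_cm, samples$theta_deg, samples$l_cm)
  y <- samples$intensity
  if (n < ncol(x)) {
    cl_abort(
      sprintf(
        "singular design: %d sample(s) cannot identify %d coefficients.",
        n, ncol(x)
      ),
      "singular_design"
    )
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    deficient <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    cl_abort(
      sprintf(
        "singular design: column(s) %s are linearly dependent on the others.",
        paste(deficient, collapse = ", ")
      ),
      "singular_design"
    )
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(x %*% beta)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  # Guard the degenerate constant-response case: a perfect fit counts as 1.
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) {
    if (ss_res <= .Machine$double.eps * max(1, sum(y^2))) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  r2 <- min(max(r2, 0), 1)
  structure(
    list(
      coefficients = poly_coefficients(unname(beta)),
      r_squared = r2,
      residual_sd = if (n > ncol(x)) sqrt(ss_res / (n - ncol(x))) else NA_real_,
      n_samples = n,
      fitted = fitted,
      residuals = resid
    ),
    class = "light_fit"
  )
}

#' @export
print.light_fit <- function(x, ...) {
  cat(sprintf(
    "<light_fit> n = %d, R^2 = %.4f, residual sd = %s\n",
    x$n_samples, x$r_squared,
    if (is.na(x$residual_sd)) "NA" else format(x$residual_sd)
  ))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.light_fit <- function(x, ...) {
  tibble::tibble(
    term = poly_term_names,
    coefficient = paste0("a", 0:9),
    estimate = as.numeric(unclass(x$coefficients))
  )
}

#' @export
glance.light_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    nobs = x$n_samples
  )
}

#' Column compensation value with the planting-direction term
#'
#' Combines the quadratic intensity prediction with the diffuse and reflected
#' fractions and a planting-direction factor:
#' `Ed = (prediction + Df + alpha) * E0 * cos(delta)`, delta in degrees.
#' The dimensionless Df and alpha are added to an intensity-scaled quantity
#' exactly as the field model prints it; with `E0 = 1` they are negligible
#' against the polynomial term.
#'
#' @inheritParams predict_intensity
#' @param stage A [stage_params()] object supplying h, theta, delta, E0, Df,
#'   alpha.
#' @return Compensation value(s), one per `l_cm`.
#' @examples
#' compensation_value(published_coefficients(), stage_params(113, 27.0), 90)
#' @export
compensation_value <- function(coeffs, stage, l_cm, calibrated_range = c(30, 180)) {
  if (!inherits(stage, "stage_params")) {
    stop_domain("`stage` must be a stage_params object.")
  }
  pred <- predict_intensity(
    coeffs, stage$height_difference_cm, stage$solar_elevation_deg, l_cm,
    calibrated_range = calibrated_range
  )
  (pred + stage$diffuse_coefficient + stage$reflectance) *
    stage$direct_solar_intensity * cos(deg2rad(stage$planting_direction_deg))
}
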