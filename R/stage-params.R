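#' Physical scene parameters for one growth stage
#'
#' Bundles the quantities that determine the light environment of the shaded
#' short-crop strip at one growth stage: the canopy height difference between
#' the tall and the short crop, the solar elevation angle, the planting
#' direction, the direct solar intensity and the diffuse and reflected light
#' fractions.
#'
#' Intensities are kept in the illuminometer's own instrument units; no lux
#' conversion is attempted. Angles are in degrees and are converted to radians
#' only inside trigonometric calls.
#'
#' @param height_difference_cm Height difference h between the tall and short
#'   canopy tops, in cm (>= 0).
#' @param solar_elevation_deg Solar elevation angle theta in degrees, strictly
#'   between 0 and 90.
#' @param planting_direction_deg Angle delta between the planting direction and
#'   the north-south axis, in degrees. Default 0 (rows on the planting axis).
#' @param direct_solar_intensity Direct solar intensity E0 (> 0), instrument
#'   units. Default 1 (relative scale).
#' @param diffuse_coefficient Fraction Df of total radiation arriving as
#'   scattered skylight, in \[0, 1\]. Default 0.15, the midpoint of the
#'   clear-day range 0.1-0.2.
#' @param reflectance Fraction alpha of light reflected by the adjacent crop
#'   strip, in \[0, 1\]. Default 0.1 (soybean row).
#'
#' @return An object of class `stage_params`: a named list with the six fields
#'   above.
#' @examples
#' podding <- stage_params(113, 27.0)
#' podding
#' @export
stage_params <- function(height_difference_cm,
                         solar_elevation_deg,
                         planting_direction_deg = 0,
                         direct_solar_intensity = 1,
                         diffuse_coefficient = 0.15,
                         reflectance = 0.1) {
  check_number(height_difference_cm, "height_difference_cm", lower = 0)
  check_number(solar_elevation_deg, "solar_elevation_deg",
    lower = 0, upper = 90, closed_lower = FALSE, closed_upper = FALSE
  )
  check_number(planting_direction_deg, "planting_direction_deg")
  check_number(direct_solar_intensity, "direct_solar_intensity",
    lower = 0, closed_lower = FALSE
  )
  check_number(diffuse_coefficient, "diffuse_coefficient", lower = 0, upper = 1)
  check_number(reflectance, "reflectance", lower = 0, upper = 1)
  structure(
    list(
      height_difference_cm = height_difference_cm,
      solar_elevation_deg = solar_elevation_deg,
      planting_direction_deg = planting_direction_deg,
      direct_solar_intensity = direct_solar_intensity,
      diffuse_coefficient = diffuse_coefficient,
      reflectance = reflectance
    ),
    class = "stage_params"
  )
}

#' @export
print.stage_params <- function(x, ...) {
  cat("<stage_params>\n")
  cat(sprintf("  height difference h: %g cm\n", x$height_difference_cm))
  cat(sprintf("  solar elevation theta: %g deg\n", x$solar_elevation_deg))
  cat(sprintf("  planting direction delta: %g deg\n", x$planting_direction_deg))
  cat(sprintf(
    "  E0: %g, Df: %g, alpha: %g\n",
    x$direct_solar_intensity, x$diffuse_coefficient, x$reflectance
  ))
  invisible(x)
}

#' Five observed growth stages of the maize-soybean system
#'
#' Height difference and solar elevation angle measured at the five key growth
#' stages of the intercropped system, from the three-leaf stage through
#' maturity. The remaining columns are the package defaults documented in
#' [stage_params()].
#'
#' @return A tibble with columns `stage`, `h_cm`, `theta_deg`, `delta_deg`,
#'   `E0`, `Df`, `alpha`.
#' @examples
#' growth_stages()
#' @export
growth_stages <- function() {
  tibble::tibble(
    stage = c("three_leaf", "flowering", "podding", "seed_filling", "maturity"),
    h_cm = c(5, 23, 113, 101, 100),
    theta_deg = c(33.8, 30.4, 27.0, 21.4, 13.9),
    delta_deg = 0,
    E0 = 1,
    Df = 0.15,
    alpha = 0.1
  )
}

#' Full factorial calibration grid of stage conditions
#'
#' The five observed (h, theta) pairs of [growth_stages()] alone cannot
#' identify the six height/angle terms of the quadratic model (five support
#' points span at most five of those columns). Crossing the observed height
#' differences with the observed solar elevations gives a full-rank design;
#' this grid is what the coefficient-recovery checks and the simulated
#' measurement tables use.
#'
#' @return A tibble with columns `h_cm` and `theta_deg`, one row per
#'   combination (25 rows).
#' @examples
#' calibration_grid()
#' @export
calibration_grid <- function() {
  tidyr::expand_grid(
    h_cm = c(5, 23, 100, 101, 113),
    theta_deg = c(13.9, 21.4, 27.0, 30.4, 33.8)
  )
}

#' Read stage parameters from JSON or CSV
#'
#' Accepts a JSON object (or a CSV row) with keys `h_cm`, `theta_deg`,
#' `delta_deg`, `E0`, `Df`, `alpha`. Missing optional keys fall back to the
#' [stage_params()] defaults; `h_cm` and `theta_deg` are required.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @param row For CSV files with several rows, which row to take (default 1).
#' @return A `stage_params` object.
#' @export
read_stage_params <- function(path, row = 1L) {
  if (!file.exists(path)) {
    stop_io(sprintf("stage parameter file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext == "csv") {
    as.list(utils::read.csv(path)[row, , drop = FALSE])
  } else {
    stop_io(sprintf("unsupported stage parameter format '%s' (use json or csv)", ext))
  }
  for (key in c("h_cm", "theta_deg")) {
    if (is.null(rec[[key]]) || is.na(rec[[key]])) {
      stop_io(sprintf("stage parameter file '%s' lacks required key '%s'", path, key))
    }
  }
  grab <- function(key, default) if (is.null(rec[[key]]) || is.na(rec[[key]])) default else rec[[key]]
  stage_params(
    height_difference_cm = rec$h_cm,
    solar_elevation_deg = rec$theta_deg,
    planting_direction_deg = grab("delta_deg", 0),
    direct_solar_intensity = grab("E0", 1),
    diffuse_coefficient = grab("Df", 0.15),
    reflectance = grab("alpha", 0.1)
  )
}

as_stage_row <- function(stage) {
  tibble::tibble(
    h_cm = stage$height_difference_cm,
    theta_deg = stage$solar_elevation_deg,
    delta_deg = stage$planting_direction_deg,
    E0 = stage$direct_solar_intensity,
    Df = stage$diffuse_coefficient,
    alpha = stage$reflectance
  )
}

#' Write stage parameters to JSON
#'
#' @param stage A `stage_params` object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_stage_params <- function(stage, path) {
  if (!inherits(stage, "stage_params")) {
    stop_domain("`stage` must be a stage_params object.")
  }
  jsonlite::write_json(as.list(as_stage_row(stage)), path,
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}
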