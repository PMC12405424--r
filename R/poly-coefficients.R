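# Fixed term order of the quadratic light-intensity model. The response is
# modeled as a full second-degree polynomial in the height difference h, the
# solar elevation angle theta (degrees) and the strip position l (cm).
poly_term_names <- c(
  "intercept", "h", "theta", "l", "h2", "h_theta", "theta_l", "theta2", "h_l", "l2"
)

#' Coefficient vector of the quadratic illumination model
#'
#' The model predicts canopy light intensity y from the crop height difference
#' h (cm), the solar elevation angle theta (degrees) and the position l (cm)
#' within the shaded strip:
#'
#' y = a0 + a1 h + a2 theta + a3 l + a4 h^2 + a5 h theta + a6 theta l +
#'     a7 theta^2 + a8 h l + a9 l^2
#'
#' The term order `(1, h, theta, l, h^2, h*theta, theta*l, theta^2, h*l, l^2)`
#' is fixed; serialization keeps the ten named entries `a0`..`a9` in that
#' order and round-trips exactly.
#'
#' @param a Numeric vector of exactly ten finite values, ordered a0..a9.
#' @return A named numeric vector of class `poly_coefficients`.
#' @examples
#' poly_coefficients(c(100, rep(0, 9)))
#' @export
poly_coefficients <- function(a) {
  if (!is.numeric(a) || length(a) != 10L || !all(is.finite(a))) {
    stop_domain("`a` must be a numeric vector of exactly ten finite values (a0..a9).")
  }
  structure(stats::setNames(as.numeric(a), paste0("a", 0:9)),
    class = "poly_coefficients"
  )
}

#' @export
print.poly_coefficients <- function(x, ...) {
  cat("<poly_coefficients> terms:", paste(poly_term_names, collapse = ", "), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Published coefficients of the quadratic illumination model
#'
#' The ten coefficients fitted by least squares on season-long field
#' measurements of light intensity at the top of the shaded soybean canopy
#' (five growth stages, six strip positions). Intensities are in the
#' illuminometer's instrument units; angles were fitted in degrees.
#'
#' @return A `poly_coefficients` vector.
#' @examples
#' published_coefficients()
#' @export
published_coefficients <- function() {
  poly_coefficients(c(3102448, -61307, -8220, -515, 235, 883, 16, -2301, 6, -0.334))
}

#' Read / write model coefficients as JSON
#'
#' The JSON object carries the ten named keys `a0`..`a9` in fixed order.
#'
#' @param path File path.
#' @return `read_coefficients()` returns a `poly_coefficients` vector;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("coefficients file not found: '%s'", path))
  }
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- paste0("a", 0:9)
  if (!all(keys %in% names(rec))) {
    stop_io(sprintf(
      "coefficients file '%s' lacks keys: %s",
      path, paste(setdiff(keys, names(rec)), collapse = ", ")
    ))
  }
  poly_coefficients(unlist(rec[keys], use.names = FALSE))
}

#' @rdname read_coefficients
#' @param coeffs A `poly_coefficients` vector.
#' @export
write_coefficients <- function(coeffs, path) {
  if (!inherits(coeffs, "poly_coefficients")) {
    stop_domain("`coeffs` must be a poly_coefficients object.")
  }
  jsonlite::write_json(as.list(unclass(coeffs)), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
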