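# Image and table I/O. PNG is the canonical lossless format; TIFF is also
# lossless; JPEG is accepted on input with a lossy-input warning (decoded via
# EBImage when available).

#' Read an RGB image
#'
#' Reads PNG or TIFF into the package's raster convention: a height x width x 3
#' integer array with values 0-255, channel order red, green, blue, left edge =
#' shaded (sun-adjacent) side. Grayscale files are replicated across channels;
#' an alpha channel is dropped. JPEG input is decoded through EBImage (if
#' installed) and triggers a warning because lossy storage breaks bit-exact
#' processing chains.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.jpg`/`.jpeg` file.
#' @return An RGB image array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("image file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_io("JPEG input requires the EBImage package; convert to PNG or TIFF.")
    }
    warning(sprintf("'%s' is JPEG (lossy); pixel values may differ from capture", path),
      call. = FALSE
    )
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    # EBImage stores width x height (x channels); transpose to height x width
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  } else {
    stop_io(sprintf("unsupported image format '.%s' (use png, tiff or jpeg)", ext))
  }
  if (is.matrix(raw)) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (dim(raw)[3L] > 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  }
  if (dim(raw)[3L] == 1L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw)[1:2], 3L))
  }
  out <- round_half_up(raw * 255)
  storage.mode(out) <- "integer"
  assert_rgb_image(out, path)
  out
}

#' Write an RGB image losslessly
#'
#' @param image RGB image array (height x width x 3, integers 0-255).
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image / 255, path, bits.per.sample = 8L)
  } else {
    stop_io(sprintf("unsupported output format '.%s' (use png or tiff)", ext))
  }
  invisible(path)
}

#' Read a light-intensity measurement table
#'
#' CSV with a header row and columns `h_cm`, `theta_deg`, `l_cm`, `intensity`
#' ('.' decimal separator).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("measurement file not found: '%s'", path))
  }
  tbl <- utils::read.csv(path)
  needed <- c("h_cm", "theta_deg", "l_cm", "intensity")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0L) {
    stop_io(sprintf(
      "measurement file '%s' lacks column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  tibble::as_tibble(tbl)
}

write_manifest <- function(path, command, params) {
  manifest <- list(
    command = command,
    package = "canopylight",
    version = as.character(utils::packageVersion("canopylight")),
    parameters = params
  )
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE, null = "null"
  )
  invisible(path)
}
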