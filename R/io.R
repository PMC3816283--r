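# File interchange: multi-channel TIFF + JSON sidecars, label masks,
# standards/perfusion CSV, calibration-curve JSON.

#' Write a multi-channel section image as TIFF with a JSON sidecar
#'
#' Channels are stored as one 32-bit float frame each, scaled into [0, 1]
#' by a common factor recorded in the sidecar (`intensity_scale`), together
#' with the physical metadata (`pixel_size_um`, `thickness_um`,
#' `channel_order`, `exposure_tag`).
#'
#' @param image a [section_image()].
#' @param path output path without extension; writes `<path>.tif` and
#'   `<path>.json`.
#' @return invisibly, the two file paths.
#' @export
write_section_image <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  scale <- max(1, max(vapply(image$channels, max, numeric(1))))
  tiff::writeTIFF(lapply(image$channels, function(ch) ch / scale),
                  paste0(path, ".tif"), bits.per.sample = 32)
  meta <- list(
    pixel_size_um = image$pixel_size, thickness_um = image$thickness,
    channel_order = names(image$channels), exposure_tag = image$exposure_tag,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, c(".tif", ".json")))
}

#' Read a section image written by [write_section_image()]
#' @param path path without extension.
#' @return a [section_image()].
#' @export
read_section_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  channels <- lapply(frames, function(f) f * meta$intensity_scale)
  names(channels) <- meta$channel_order
  section_image(channels, meta$pixel_size_um, meta$thickness_um,
                meta$exposure_tag)
}

#' Write an autoradiograph as TIFF with a JSON sidecar
#' @param ar a [generate_autoradiograph()] object.
#' @param path output path without extension.
#' @return invisibly, the file paths.
#' @export
write_autoradiograph <- function(ar, path) {
  stopifnot(inherits(ar, "autoradiograph"))
  scale <- max(1, max(ar$activity))
  tiff::writeTIFF(ar$activity / scale, paste0(path, ".tif"),
                  bits.per.sample = 32)
  meta <- list(pixel_size_um = ar$pixel_size,
               downsample_factor = ar$downsample_factor,
               shift_px = ar$shift_px, background = ar$background,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, c(".tif", ".json")))
}

#' Read an autoradiograph written by [write_autoradiograph()]
#' @param path path without extension.
#' @return an `autoradiograph` object.
#' @export
read_autoradiograph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  act <- tiff::readTIFF(paste0(path, ".tif")) * meta$intensity_scale
  structure(
    list(activity = act, downsample_factor = meta$downsample_factor,
         pixel_size = meta$pixel_size_um,
         shift_px = as.integer(meta$shift_px),
         background = meta$background),
    class = "autoradiograph"
  )
}

#' Write an integer label mask as a 16-bit TIFF
#' @param mask integer label matrix (0 = background, labels < 65536).
#' @param path output `.tif` path.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path `.tif` path.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Serialize a fitted standard curve to JSON
#' @param curve a [fit_standard_curve()] object.
#' @param path output `.json` path.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "standard_curve"))
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         r_squared = curve$r_squared, n_points = curve$n_points,
         through_origin = curve$through_origin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a standard curve serialized by [write_curve_json()]
#' @param path `.json` path.
#' @return a `standard_curve` (without the underlying `lm`).
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_points = x$n_points, through_origin = x$through_origin,
         fit = NULL),
    class = "standard_curve"
  )
}
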