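#' Multi-channel tissue section image
#'
#' Container for a cryosection imaged in several fluorescence channels on a
#' common pixel grid, together with the physical metadata needed for
#' quantification: the lateral pixel size (um/pixel) and the section
#' thickness (um, 20 by default for cryotome sections).
#'
#' @param channels named list of numeric matrices, all of identical
#'   dimensions, intensities in arbitrary units >= 0.
#' @param pixel_size lateral pixel size in um/pixel (> 0).
#' @param thickness section thickness in um (> 0, default 20).
#' @param exposure_tag free-text acquisition label (e.g. "15ms_gain615").
#' @return an object of class `section_image`.
#' @examples
#' img <- section_image(list(r123 = matrix(1, 4, 4)), pixel_size = 2)
#' img
#' @export
section_image <- function(channels, pixel_size, thickness = 20,
                          exposure_tag = "simulated") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1))) ||
      length(unique(dims)) != 1L) {
    stop("all channels must be matrices sharing one grid shape", call. = FALSE)
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop("channel intensities must be >= 0", call. = FALSE)
  }
  check_positive(pixel_size, "pixel_size")
  check_positive(thickness, "thickness")
  structure(
    list(channels = channels, pixel_size = pixel_size, thickness = thickness,
         exposure_tag = exposure_tag),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("section_image: %d x %d px, %g um/px, %g um thick\n",
              d[1], d[2], x$pixel_size, x$thickness))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  exposure:", x$exposure_tag, "\n")
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$channels[[1]])
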