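#' Processing parameters
#'
#' Bundles every tunable of the image-processing pipeline with its default.
#' Defaults reproduce the method's standard configuration: the darkest 75%
#' of pixels (by B+R sum) are background, dental components must exceed
#' 2000 pixels and solidity 0.5, and images above 5 MB of raw pixel data
#' are downscaled before processing.
#'
#' @param background_fraction Fraction of pixels (by darkness of the B+R
#'   channel sum) treated as background; foreground is the complement.
#'   Must lie strictly between 0 and 1. Default 0.75.
#' @param min_region_size Minimum pixel count (strict) for a connected
#'   component to count as dental. Default 2000.
#' @param min_solidity Minimum solidity (strict; component area divided by
#'   convex-hull area) for a dental component, in (0, 1]. Default 0.5.
#' @param delta Threshold separating level-1 from level-2 non-visible
#'   plaque on the non-positive G-B axis. Either \code{"auto"} (computed
#'   per image as minus the absolute difference of the mean blue and green
#'   channels over the dental area, see \code{\link{auto_delta}}) or a
#'   non-positive number. Default \code{"auto"}.
#' @param artifact_intensity_floor 8-bit intensity: pixels whose minimum
#'   channel value reaches this floor are treated as specular (near-white)
#'   artifacts and removed from the dental mask. Default 240.
#' @param max_image_bytes Raw-pixel byte budget (H x W x 3); larger images
#'   are downscaled by the smallest integer factor that fits. Default 5e6.
#' @param crop Optional axis-aligned crop rectangle applied before any
#'   processing: integer vector \code{c(row0, row1, col0, col1)}, 0-based,
#'   half-open (pixels with \code{row0 <= row < row1} are kept).
#'   \code{NULL} (default) disables cropping.
#'
#' @return An object of class \code{processing_params}.
#' @examples
#' processing_params()
#' processing_params(min_region_size = 500, delta = -30)
#' @export
processing_params <- function(background_fraction = 0.75,
                              min_region_size = 2000,
                              min_solidity = 0.5,
                              delta = "auto",
                              artifact_intensity_floor = 240,
                              max_image_bytes = 5e6,
                              crop = NULL) {
  stopifnot(is.numeric(background_fraction), length(background_fraction) == 1)
  if (!(background_fraction > 0 && background_fraction < 1))
    plaquant_error("plaquant_parameter_error",
                   "background_fraction must lie strictly between 0 and 1")
  if (!(is.numeric(min_region_size) && min_region_size >= 1))
    plaquant_error("plaquant_parameter_error", "min_region_size must be >= 1")
  if (!(is.numeric(min_solidity) && min_solidity > 0 && min_solidity <= 1))
    plaquant_error("plaquant_parameter_error", "min_solidity must be in (0, 1]")
  if (!identical(delta, "auto")) {
    if (!(is.numeric(delta) && length(delta) == 1 && delta <= 0))
      plaquant_error("plaquant_parameter_error",
                     "delta must be \"auto\" or a non-positive number")
    delta <- as.numeric(delta)
  }
  if (!(is.numeric(artifact_intensity_floor) && artifact_intensity_floor >= 0))
    plaquant_error("plaquant_parameter_error",
                   "artifact_intensity_floor must be a non-negative intensity")
  if (!(is.numeric(max_image_bytes) && max_image_bytes > 0))
    plaquant_error("plaquant_parameter_error", "max_image_bytes must be positive")
  if (!is.null(crop)) {
    crop <- as.integer(crop)
    if (length(crop) != 4 || crop[1] < 0 || crop[3] < 0 ||
        crop[2] <= crop[1] || crop[4] <= crop[3])
      plaquant_error("plaquant_parameter_error",
                     "crop must be c(row0, row1, col0, col1), half-open, non-empty")
  }
  structure(
    list(background_fraction = background_fraction,
         min_region_size = as.numeric(min_region_size),
         min_solidity = min_solidity,
         delta = delta,
         artifact_intensity_floor = as.numeric(artifact_intensity_floor),
         max_image_bytes = as.numeric(max_image_bytes),
         crop = crop),
    class = "processing_params"
  )
}

#' @export
print.processing_params <- function(x, ...) {
  cat("Plaque processing parameters:\n")
  cat(sprintf("  background fraction (B+R quantile): %.3f\n", x$background_fraction))
  cat(sprintf("  min component size: > %g px;  min solidity: > %g\n",
              x$min_region_size, x$min_solidity))
  cat(sprintf("  delta: %s;  artifact floor: %g;  max image bytes: %g\n",
              if (identical(x$delta, "auto")) "auto" else format(x$delta),
              x$artifact_intensity_floor, x$max_image_bytes))
  if (!is.null(x$crop))
    cat(sprintf("  crop: rows [%d, %d), cols [%d, %d)\n",
                x$crop[1], x$crop[2], x$crop[3], x$crop[4]))
  invisible(x)
}
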