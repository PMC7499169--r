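#' Construct a UV dentition image
#'
#' Wraps an 8-bit RGB raster of a fluorescein-dyed dentition view together
#' with its acquisition timestamp. Pixels are stored row-major as an
#' H x W x 3 integer array (R, G, B planes) with values in [0, 255];
#' origin is the top-left corner.
#'
#' @param pixels H x W x 3 numeric array; values must lie in [0, 255].
#' @param timestamp Acquisition time (\code{POSIXct}, or a string parsed
#'   as ISO-8601; stored timezone-naive as UTC).
#' @param source_path Optional path the image was read from.
#' @return An object of class \code{uv_image}.
#' @seealso \code{\link{read_uv_image}}
#' @export
uv_image <- function(pixels, timestamp = NULL, source_path = NA_character_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    plaquant_error("plaquant_parameter_error", "pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    plaquant_error("plaquant_parameter_error", "channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         timestamp = parse_timestamp(timestamp),
         source_path = source_path),
    class = "uv_image"
  )
}

parse_timestamp <- function(x) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(NULL)
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                  "%Y-%m-%d %H:%M:%S",
                                                  "%Y-%m-%d"))
  if (is.na(out))
    plaquant_error("plaquant_config_error",
                   paste0("cannot parse timestamp: ", x))
  out
}

#' Read a UV image from disk
#'
#' Reads PNG, JPEG or TIFF (8-bit per channel) into a \code{\link{uv_image}}.
#' Greyscale images are replicated across channels; an alpha plane, if
#' present, is dropped. Images whose raw pixel payload (H x W x 3 bytes)
#' exceeds \code{max_bytes} are downscaled by the smallest integer factor
#' that brings them under the limit, preserving aspect ratio.
#'
#' @param path Image file path.
#' @param timestamp Optional acquisition timestamp (see \code{\link{uv_image}}).
#' @param max_bytes Raw-pixel byte budget; \code{Inf} disables downscaling.
#' @return A \code{uv_image}.
#' @export
read_uv_image <- function(path, timestamp = NULL, max_bytes = 5e6) {
  if (!file.exists(path))
    plaquant_error("plaquant_io_error", paste0("image not found: ", path))
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2) {
    px <- array(px, dim = c(dim(px), 3))            # greyscale -> 3 planes
  } else if (dim(px)[3] > 3) {
    px <- px[, , 1:3, drop = FALSE]                 # drop alpha
  } else if (dim(px)[3] < 3) {
    px <- array(px[, , 1], dim = c(dim(px)[1:2], 3))
  }
  px <- aperm(px, c(2, 1, 3))                       # EBImage is W x H
  px <- round(px * 255)
  out <- uv_image(px, timestamp = timestamp, source_path = path)
  downscale_to_bytes(out, max_bytes)
}

#' Downscale an image to fit a byte budget
#'
#' Block-averages the image by the smallest integer factor \code{k} such
#' that \code{ceiling(H/k) * ceiling(W/k) * 3 <= max_bytes}. Returns the
#' input untouched when it already fits.
#'
#' @param image A \code{uv_image}.
#' @param max_bytes Raw-pixel byte budget.
#' @return A \code{uv_image}, possibly smaller.
#' @export
downscale_to_bytes <- function(image, max_bytes) {
  stopifnot(inherits(image, "uv_image"))
  d <- dim(image$pixels)
  if (is.infinite(max_bytes) || prod(d) <= max_bytes) return(image)
  k <- 2L
  while (ceiling(d[1] / k) * ceiling(d[2] / k) * 3 > max_bytes) k <- k + 1L
  image$pixels <- block_mean(image$pixels, k)
  image
}

# Integer-factor block mean of an H x W x 3 array, rounded back to 8-bit.
block_mean <- function(px, k) {
  d <- dim(px)
  h2 <- ceiling(d[1] / k); w2 <- ceiling(d[2] / k)
  out <- array(0L, dim = c(h2, w2, 3))
  ri <- ((seq_len(d[1]) - 1L) %/% k) + 1L
  ci <- ((seq_len(d[2]) - 1L) %/% k) + 1L
  n <- tapply(rep(1, d[1] * d[2]),
              list(ri[row(px[, , 1])], ci[col(px[, , 1])]), sum)
  for (ch in 1:3) {
    s <- tapply(px[, , ch], list(ri[row(px[, , ch])], ci[col(px[, , ch])]), sum)
    out[, , ch] <- as.integer(round(s / n))
  }
  out
}

# channel plane as a matrix (slicing H x W x 3 drops dims when H or W is 1)
channel <- function(image, i) {
  v <- image$pixels[, , i, drop = FALSE]
  dim(v) <- dim(v)[1:2]
  v
}

#' Crop an image to a half-open rectangle
#'
#' @param image A \code{uv_image}.
#' @param crop Integer vector \code{c(row0, row1, col0, col1)}, 0-based,
#'   half-open; clipped to the image bounds.
#' @return The cropped \code{uv_image}.
#' @export
crop_image <- function(image, crop) {
  stopifnot(inherits(image, "uv_image"))
  if (is.null(crop)) return(image)
  d <- dim(image$pixels)
  r0 <- max(0L, crop[1]); r1 <- min(d[1], crop[2])
  c0 <- max(0L, crop[3]); c1 <- min(d[2], crop[4])
  if (r1 <= r0 || c1 <= c0)
    plaquant_error("plaquant_parameter_error", "crop rectangle is empty after clipping")
  image$pixels <- image$pixels[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE]
  image
}

#' @export
print.uv_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("UV image %d x %d px (8-bit RGB)", d[1], d[2]))
  if (!is.null(x$timestamp))
    cat(sprintf(", taken %s", format(x$timestamp, "%Y-%m-%d %H:%M:%S")))
  if (!is.na(x$source_path)) cat(sprintf("\n  source: %s", x$source_path))
  cat("\n")
  invisible(x)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

#' Write an H x W x 3 8-bit RGB array as PNG
#'
#' @param pixels H x W x 3 array of values in [0, 255].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rgb_png <- function(pixels, path) {
  png::writePNG(pixels / 255, target = path)
  invisible(path)
}
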