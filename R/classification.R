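#' Green-minus-blue difference map
#'
#' Computes the signed per-pixel difference G - B over the dental area.
#' Fluorescein-stained plaque fluoresces green (G > B) while clean enamel
#' fluoresces blue (B > G), so this difference carries the entire
#' plaque/non-plaque contrast.
#'
#' @param image A \code{\link{uv_image}}.
#' @param mask A \code{dental_mask} (or logical matrix) within the image
#'   bounds.
#' @return A \code{gb_map}: integer matrix in [-255, 255] with \code{NA}
#'   outside the dental area.
#' @export
gb_map <- function(image, mask) {
  stopifnot(inherits(image, "uv_image"))
  m <- as_mask_matrix(mask)
  if (!all(dim(m) == dim(image$pixels)[1:2]))
    plaquant_error("plaquant_parameter_error", "mask does not match image dimensions")
  v <- channel(image, 2) - channel(image, 3)
  v[!m] <- NA_integer_
  structure(v, class = "gb_map")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "dental_mask")) mask$mask
  else if (is.logical(mask) && is.matrix(mask)) mask
  else plaquant_error("plaquant_parameter_error",
                      "mask must be a dental_mask or logical matrix")
}

#' Automatic delta threshold
#'
#' The delta threshold separating level-1 from level-2 non-visible plaque
#' is resolved automatically as the absolute difference between the mean
#' blue and mean green channel values over the dental area, taken with a
#' negative sign so that it thresholds the non-positive side of the G-B
#' axis: \code{delta = -|mean(B) - mean(G)|}.
#'
#' @param image A \code{\link{uv_image}}.
#' @param mask Dental mask (see \code{\link{gb_map}}).
#' @return Non-positive number.
#' @export
auto_delta <- function(image, mask) {
  m <- as_mask_matrix(mask)
  if (!any(m))
    plaquant_error("plaquant_empty_dental_area", "cannot compute delta on an empty mask")
  g <- mean(channel(image, 2)[m])
  b <- mean(channel(image, 3)[m])
  -abs(b - g)
}

#' G-B histogram of the dental area
#'
#' Integer counts per G-B value, one bin per intensity step from -255 to
#' 255 (511 bins). Counts sum to the number of dental pixels.
#'
#' @param gb A \code{\link{gb_map}}.
#' @return A \code{gb_histogram}: named integer vector of length 511.
#' @export
gb_histogram <- function(gb) {
  stopifnot(inherits(gb, "gb_map"))
  v <- gb[!is.na(gb)]
  counts <- tabulate(as.integer(v) + 256L, nbins = 511L)
  structure(setNames(counts, -255:255), class = "gb_histogram")
}

#' Histogram of first-approximation non-visible plaque pixels
#'
#' Restricts the histogram to the pixels of the non-visible plaque first
#' approximation: dental pixels with G - B <= 0, G > 0 and B > 0. These
#' are the histograms compared between a moment and its reference to
#' resolve the l threshold.
#'
#' @param image A \code{\link{uv_image}}.
#' @param mask Dental mask.
#' @return A \code{gb_histogram} (positive-side bins are all zero).
#' @export
nonvisible_histogram <- function(image, mask) {
  m <- as_mask_matrix(mask)
  g <- channel(image, 2); b <- channel(image, 3)
  sel <- m & (g - b) <= 0L & g > 0L & b > 0L
  counts <- tabulate((g - b)[sel] + 256L, nbins = 511L)
  structure(setNames(counts, -255:255), class = "gb_histogram")
}

#' Automatic l threshold from current vs reference histograms
#'
#' The l threshold separating level-2 non-visible plaque from non-plaque
#' is the first G-B value, scanning from -255 upward to 0, at which the
#' current moment's non-visible-plaque histogram count strictly exceeds
#' the reference moment's. When no such value exists (e.g. the moment is
#' compared against itself) l falls back to \code{delta}, leaving the
#' level-2 region empty.
#'
#' @param current_hist,reference_hist \code{gb_histogram}s of the current
#'   and reference images of the same patient (see
#'   \code{\link{nonvisible_histogram}}).
#' @param delta Fallback value (the delta threshold in force).
#' @return Signed intensity l with \code{l <= 0}; attribute
#'   \code{"fallback"} is \code{TRUE} when the delta fallback was used.
#' @export
auto_l <- function(current_hist, reference_hist, delta) {
  stopifnot(inherits(current_hist, "gb_histogram"),
            inherits(reference_hist, "gb_histogram"))
  neg <- 1:256                                     # bins -255 .. 0
  hit <- which(current_hist[neg] > reference_hist[neg])
  if (length(hit) == 0)
    return(structure(delta, fallback = TRUE))
  structure(-256 + hit[1], fallback = FALSE)
}

#' Classify dental pixels into plaque regions
#'
#' Partitions the dental area by the signed G-B difference:
#' \describe{
#'   \item{VISIBLE}{G - B > 0 (visible plaque).}
#'   \item{NV1}{delta <= G - B <= 0 (level-1 non-visible plaque: risk of
#'     becoming plaque in the following hours).}
#'   \item{NV2}{l <= G - B < delta (level-2: risk in the following days).}
#'   \item{NONPLAQUE}{G - B < l, or a dental pixel with G = 0 or B = 0
#'     (the non-visible classes are defined only where both channels are
#'     positive).}
#' }
#' Non-dental pixels are OUTSIDE. Both boundary values belong to the
#' upper class: G-B equal to delta is NV1, equal to l is NV2.
#'
#' @param gb A \code{\link{gb_map}}.
#' @param image The source \code{\link{uv_image}} (for the G > 0, B > 0
#'   guard).
#' @param delta,l Thresholds with \code{l <= delta <= 0}.
#' @return A \code{region_labels} object: integer matrix of class codes
#'   (see \code{\link{plaque_classes}}) plus \code{delta_used},
#'   \code{l_used}.
#' @export
classify_plaque <- function(gb, image, delta, l) {
  stopifnot(inherits(gb, "gb_map"), inherits(image, "uv_image"))
  if (!(l <= delta && delta <= 0))
    plaquant_error("plaquant_parameter_error",
                   sprintf("need l <= delta <= 0, got delta = %g, l = %g", delta, l))
  m <- !is.na(gb)
  d <- unclass(gb)
  g <- channel(image, 2); b <- channel(image, 3)
  lab <- matrix(.CLASS_CODES[["OUTSIDE"]], nrow(d), ncol(d))
  lab[m & d > 0L] <- .CLASS_CODES[["VISIBLE"]]
  nonpos <- m & d <= 0L
  guard <- nonpos & (g == 0L | b == 0L)            # pure-black channels: no risk class
  lab[guard] <- .CLASS_CODES[["NONPLAQUE"]]
  ok <- nonpos & !guard
  lab[ok & d >= delta] <- .CLASS_CODES[["NV1"]]
  lab[ok & d < delta & d >= l] <- .CLASS_CODES[["NV2"]]
  lab[ok & d < l] <- .CLASS_CODES[["NONPLAQUE"]]
  structure(
    list(labels = lab, delta_used = as.numeric(delta), l_used = as.numeric(l)),
    class = "region_labels"
  )
}

#' Count pixels per class
#'
#' @param labels A \code{region_labels} object.
#' @return Named integer vector of pixel counts for VISIBLE, NV1, NV2,
#'   NONPLAQUE and OUTSIDE.
#' @export
class_counts <- function(labels) {
  stopifnot(inherits(labels, "region_labels"))
  counts <- tabulate(labels$labels + 1L, nbins = 5L)
  setNames(counts[c(2, 3, 4, 5, 1)],
           c("VISIBLE", "NV1", "NV2", "NONPLAQUE", "OUTSIDE"))
}

#' @export
print.region_labels <- function(x, ...) {
  cc <- class_counts(x)
  dental <- sum(cc[c("VISIBLE", "NV1", "NV2", "NONPLAQUE")])
  cat(sprintf("Plaque region labels (%d dental px; delta = %.2f, l = %.2f):\n",
              dental, x$delta_used, x$l_used))
  for (nm in c("VISIBLE", "NV1", "NV2", "NONPLAQUE"))
    cat(sprintf("  %-9s %8d px  (%6.2f%%)\n", nm, cc[[nm]],
                if (dental > 0) 100 * cc[[nm]] / dental else 0))
  invisible(x)
}

# default display palette (RGB 0-255 per class)
.DEFAULT_PALETTE <- list(
  OUTSIDE   = c(0, 0, 0),
  VISIBLE   = c(0, 255, 0),
  NV1       = c(255, 0, 0),
  NV2       = c(255, 165, 0),
  NONPLAQUE = c(0, 0, 255)
)

#' Render labels as an RGB image
#'
#' Paints each class with the standard palette: blue non-plaque, green
#' visible plaque, red level-1 non-visible plaque, orange level-2
#' non-visible plaque, black outside the dental area.
#'
#' @param labels A \code{region_labels} object.
#' @param palette Named list of RGB triplets (0-255) per class name;
#'   defaults can be overridden per class.
#' @return H x W x 3 array of values in [0, 255].
#' @export
label_image <- function(labels, palette = list()) {
  stopifnot(inherits(labels, "region_labels"))
  pal <- modifyList(.DEFAULT_PALETTE, palette)
  lab <- labels$labels
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (nm in names(.CLASS_CODES)) {
    sel <- lab == .CLASS_CODES[[nm]]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- pal[[nm]][ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' @export
plot.region_labels <- function(x, ...) {
  img <- label_image(x) / 255
  op <- par(mar = c(0.5, 0.5, 2, 0.5)); on.exit(par(op))
  plot(c(0, ncol(x$labels)), c(0, nrow(x$labels)), type = "n", axes = FALSE,
       xlab = "", ylab = "", asp = 1,
       main = "green: visible | red: NV1 | orange: NV2 | blue: non-plaque")
  graphics::rasterImage(img, 0, 0, ncol(x$labels), nrow(x$labels))
  invisible(x)
}

#' Write a G-B histogram as two-column CSV
#'
#' @param hist A \code{gb_histogram}.
#' @param path Output path; columns \code{gb_value}, \code{count}.
#' @return The path, invisibly.
#' @export
write_gb_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "gb_histogram"))
  write.csv(data.frame(gb_value = -255:255, count = as.integer(hist)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a G-B histogram
#'
#' Draws the dental-area G-B histogram with a vertical marker at G-B = 0
#' separating visible plaque (right) from non-visible plaque and
#' non-plaque (left). A reference-moment histogram can be overlaid.
#'
#' @param hist A \code{gb_histogram}.
#' @param reference Optional second \code{gb_histogram} drawn for
#'   comparison.
#' @param main Plot title.
#' @return Invisibly, \code{hist}.
#' @export
plot_gb_histogram <- function(hist, reference = NULL, main = "G-B histogram") {
  stopifnot(inherits(hist, "gb_histogram"))
  v <- -255:255
  plot(v, as.numeric(hist), type = "l", col = "black", lwd = 1.5,
       xlab = "G - B", ylab = "pixel count", main = main)
  if (!is.null(reference))
    lines(v, as.numeric(reference), col = "grey55", lty = 2)
  abline(v = 0, col = "red3")
  if (!is.null(reference))
    legend("topright", legend = c("current", "reference"),
           col = c("black", "grey55"), lty = c(1, 2), bty = "n")
  invisible(hist)
}
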