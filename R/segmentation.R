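#' Brightness threshold from the B+R channel sum
#'
#' Computes the intensity threshold separating dark background from bright
#' (dental) foreground. The blue and red channels are summed per pixel
#' (range 0-510) and the threshold is the \code{background_fraction}
#' quantile of that sum, taken as the sorted value at rank
#' \code{ceiling(background_fraction * N)}: the darkest
#' \code{background_fraction} of pixels are background. Foreground
#' membership is strict (\code{B + R > threshold}); ties at the threshold
#' go to the background side.
#'
#' @param image A \code{\link{uv_image}}.
#' @param background_fraction Fraction in (0, 1); default 0.75.
#' @return The threshold (single number, 0-510). A constant image (zero
#'   spread in B+R) raises a degenerate-image warning; its foreground is
#'   empty since no value is strictly above the threshold.
#' @export
brightness_threshold <- function(image, background_fraction = 0.75) {
  stopifnot(inherits(image, "uv_image"))
  if (!(background_fraction > 0 && background_fraction < 1))
    plaquant_error("plaquant_parameter_error",
                   "background_fraction must lie strictly between 0 and 1")
  br <- channel(image, 3) + channel(image, 1)
  v <- sort(as.vector(br))
  if (v[1] == v[length(v)])
    plaquant_warning("plaquant_degenerate_image",
                     "constant image: B+R has zero spread, foreground is empty")
  v[ceiling(background_fraction * length(v))]
}

#' Remove isolated foreground pixels
#'
#' A foreground pixel with no foreground neighbor in its 8-neighborhood is
#' set to background; all other pixels are unchanged.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
remove_isolated_pixels <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  mask & (neighbor_count(mask) > 0L)
}

# 8-neighborhood foreground count via zero-padded shifts.
neighbor_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- mask
  n <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + p[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
  }
  n
}

#' Remove bright specular artifacts from a mask
#'
#' Near-white specular highlights (flash reflections on saliva or enamel)
#' are bright in every channel, unlike dental signal which is blue- or
#' green-dominated. Pixels whose minimum channel value reaches
#' \code{artifact_intensity_floor} are removed from the mask.
#'
#' @param mask Logical matrix.
#' @param image The \code{\link{uv_image}} the mask belongs to.
#' @param artifact_intensity_floor 8-bit intensity floor; default 240.
#' @return Logical matrix with artifact pixels cleared.
#' @export
remove_bright_artifacts <- function(mask, image, artifact_intensity_floor = 240) {
  stopifnot(inherits(image, "uv_image"), is.logical(mask))
  minc <- pmin(channel(image, 1), channel(image, 2), channel(image, 3))
  mask & !(minc >= artifact_intensity_floor)
}

#' Label connected components with 8-connectivity
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background), labels
#'   compact from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)            # 4-connected labels
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  # merge labels that touch diagonally to obtain 8-connectivity
  pairs <- diagonal_pairs(lab)
  if (nrow(pairs) > 0) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(k), find, integer(1))
    remap <- match(root, sort(unique(root)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# distinct positive label pairs that are diagonal neighbors
diagonal_pairs <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  out <- matrix(integer(0), ncol = 2)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(h - 1L), if (sh[2] == 1L) seq_len(w - 1L) else 2:w]
    b <- lab[2:h, if (sh[2] == 1L) 2:w else seq_len(w - 1L)]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) out <- rbind(out, unique(cbind(a[sel], b[sel])))
  }
  unique(out)
}

#' Solidity of a pixel set
#'
#' Solidity is the component's pixel count divided by the pixel count of
#' its convex hull (the hull of the pixel centers, rasterized back onto
#' the grid). Degenerate hulls (all pixel centers collinear) have solidity
#' 1 by convention.
#'
#' @param rows,cols Integer vectors of pixel coordinates (1-based).
#' @return Solidity in (0, 1].
#' @export
pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  stopifnot(n == length(cols), n >= 1)
  pts <- unique(cbind(cols, rows))            # x = col, y = row
  if (nrow(pts) < 3) return(1)
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  if (nrow(hull) < 3 || polygon_area(hull) == 0) return(1)
  n / convex_hull_pixels(hull,
                         rmin = min(rows), rmax = max(rows),
                         cmin = min(cols), cmax = max(cols))
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# number of grid pixels whose center lies inside or on the convex polygon
convex_hull_pixels <- function(hull, rmin, rmax, cmin, cmax) {
  # orient counter-clockwise (in row/col coordinates)
  x <- hull[, 1]; y <- hull[, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) {
    hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
    x <- hull[, 1]; y <- hull[, 2]
  }
  cc <- rep(cmin:cmax, times = rmax - rmin + 1)
  rr <- rep(rmin:rmax, each = cmax - cmin + 1)
  inside <- rep(TRUE, length(cc))
  nv <- nrow(hull)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (x[j] - x[i]) * (rr - y[i]) - (y[j] - y[i]) * (cc - x[i])
    inside <- inside & (cross >= -1e-9)
  }
  sum(inside)
}

#' Filter connected components by size and solidity
#'
#' Labels the mask with 8-connectivity and keeps only components whose
#' pixel count strictly exceeds \code{min_region_size} and whose solidity
#' strictly exceeds \code{min_solidity}; everything else is removed as
#' non-dental (gingiva remnants, lips, noise blobs).
#'
#' @param mask Logical matrix.
#' @param min_region_size Strict lower bound on component pixel count.
#' @param min_solidity Strict lower bound on solidity.
#' @return A \code{dental_mask}: list with \code{mask} (logical),
#'   \code{components} (integer labels 1..K, 0 outside), and per-component
#'   \code{sizes} and \code{solidity}.
#' @export
filter_components <- function(mask, min_region_size = 2000, min_solidity = 0.5) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L)
    plaquant_error("plaquant_empty_dental_area",
                   "no connected component survives segmentation")
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  sol <- numeric(k)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  for (i in seq_len(k)) {
    sel <- labv == i
    sol[i] <- pixel_solidity(idx[sel, 1], idx[sel, 2])
  }
  keep <- which(sizes > min_region_size & sol > min_solidity)
  if (length(keep) == 0)
    plaquant_error("plaquant_empty_dental_area",
                   "no component passes the size/solidity filters")
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0L] <- remap[labv]
  structure(
    list(mask = out > 0L,
         components = out,
         n_components = length(keep),
         sizes = sizes[keep],
         solidity = sol[keep]),
    class = "dental_mask"
  )
}

#' Segment the dental area of a UV image
#'
#' Full dental-area segmentation: optional crop, then thresholding of the
#' B+R channel sum (darkest \code{background_fraction} of pixels become
#' background), removal of near-white specular artifacts and of isolated
#' pixels, and connected-component filtering by size and solidity. The
#' result marks teeth only; gingiva and background are excluded.
#'
#' @param image A \code{\link{uv_image}}.
#' @param params A \code{\link{processing_params}} object.
#' @return A \code{dental_mask} (see \code{\link{filter_components}}) with
#'   the applied brightness threshold attached as attribute
#'   \code{"threshold"}. Deterministic for fixed inputs.
#' @examples
#' spec <- scene_spec(seed = 1)
#' sc <- render_scene(spec)
#' dm <- segment_dental_area(sc$image, processing_params())
#' dm$n_components
#' @export
segment_dental_area <- function(image, params = processing_params()) {
  stopifnot(inherits(image, "uv_image"), inherits(params, "processing_params"))
  image <- crop_image(image, params$crop)
  thr <- brightness_threshold(image, params$background_fraction)
  fg <- (channel(image, 3) + channel(image, 1)) > thr
  fg <- remove_bright_artifacts(fg, image, params$artifact_intensity_floor)
  fg <- remove_isolated_pixels(fg)
  if (!any(fg))
    plaquant_error("plaquant_empty_dental_area",
                   "empty foreground after thresholding and artifact removal")
  dm <- filter_components(fg, params$min_region_size, params$min_solidity)
  attr(dm, "threshold") <- thr
  dm
}

#' @export
print.dental_mask <- function(x, ...) {
  cat(sprintf("Dental mask: %d px in %d component(s) of %d x %d raster\n",
              sum(x$mask), x$n_components, nrow(x$mask), ncol(x$mask)))
  cat(sprintf("  component sizes: %s\n", paste(x$sizes, collapse = ", ")))
  cat(sprintf("  solidity: %s\n", paste(sprintf("%.3f", x$solidity), collapse = ", ")))
  invisible(x)
}
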