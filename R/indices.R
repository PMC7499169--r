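#' Area percentage of a plaque class
#'
#' @param labels A \code{region_labels} object.
#' @param cls Class name: \code{"VISIBLE"}, \code{"NV1"}, \code{"NV2"} or
#'   \code{"NONPLAQUE"}.
#' @return 100 x (pixels of the class) / (dental pixels).
#' @export
area_percent <- function(labels, cls) {
  cls <- match.arg(cls, c("VISIBLE", "NV1", "NV2", "NONPLAQUE"))
  cc <- class_counts(labels)
  dental <- sum(cc[c("VISIBLE", "NV1", "NV2", "NONPLAQUE")])
  if (dental == 0)
    plaquant_error("plaquant_empty_dental_area", "no dental pixels in label raster")
  100 * cc[[cls]] / dental
}

#' API index (area per intensity)
#'
#' A 0-100 index combining the extent and stain intensity of visible
#' plaque: the visible-plaque fraction of the dental area multiplied by
#' the mean G-B intensity over visible pixels normalized to the 8-bit
#' range,
#' \deqn{API = \frac{n_{vis}}{n_{dental}} \cdot \frac{\overline{G-B}_{vis}}{255} \cdot 100.}
#' It is 0 when no visible plaque is present and 100 when the entire
#' dental area is visible plaque at saturated intensity. The product form
#' is a documented reconstruction: it is the simplest formula bounded to
#' [0, 100] that increases with both plaque extent and stain intensity.
#'
#' @param labels A \code{region_labels} object.
#' @param gb The matching \code{\link{gb_map}}.
#' @return API index in [0, 100].
#' @export
api_index <- function(labels, gb) {
  stopifnot(inherits(labels, "region_labels"), inherits(gb, "gb_map"))
  lab <- labels$labels
  dental <- sum(lab != .CLASS_CODES[["OUTSIDE"]])
  if (dental == 0)
    plaquant_error("plaquant_empty_dental_area", "no dental pixels in label raster")
  vis <- lab == .CLASS_CODES[["VISIBLE"]]
  nvis <- sum(vis)
  if (nvis == 0) return(0)
  mean_int <- mean(gb[vis])
  (nvis / dental) * (mean_int / 255) * 100
}

#' Area growth index
#'
#' Growth rate of plaque area per unit time, in percentage points of the
#' dental area per hour, measured against the reference moment.
#'
#' @param area_now Current area percentage (0-100).
#' @param area_ref Reference-moment area percentage (typically ~0 after
#'   professional cleaning).
#' @param elapsed_hours Hours elapsed since the reference moment; must be
#'   positive.
#' @return Percent area per hour (may be negative if plaque decreased).
#' @export
area_growth_index <- function(area_now, area_ref, elapsed_hours) {
  if (!(elapsed_hours > 0))
    plaquant_error("plaquant_reference_moment_error",
                   "growth index undefined for the reference moment (elapsed time must be > 0)")
  (area_now - area_ref) / elapsed_hours
}

#' Area time index
#'
#' Extrapolated time, in days, for the plaque area to reach 100% of the
#' dental area, assuming the growth rate stays constant:
#' \code{(100 - area_now) / growth_rate / 24}.
#'
#' @param area_now Current area percentage.
#' @param growth_rate Growth rate in percent area per hour.
#' @return Days to full coverage; \code{0} when the area is already at or
#'   above 100%; \code{NA} (not computable) when the rate is zero or
#'   negative.
#' @export
area_time_index <- function(area_now, growth_rate) {
  if (area_now >= 100) return(0)
  if (!(growth_rate > 0)) return(NA_real_)
  (100 - area_now) / growth_rate / 24
}

#' Normalization factor between two dental masks
#'
#' When an experiment spans several moments of one patient, the images
#' are normalized in their number of dental pixels: every cross-moment
#' comparison uses area percentages (which are scale invariant) and this
#' ratio is recorded so absolute pixel counts remain comparable.
#'
#' @param current,reference \code{dental_mask} objects (or logical
#'   matrices) of the current and reference images.
#' @return reference dental pixel count / current dental pixel count.
#' @export
normalization_factor <- function(current, reference) {
  nc <- sum(as_mask_matrix(current))
  nr <- sum(as_mask_matrix(reference))
  if (nc == 0 || nr == 0)
    plaquant_error("plaquant_empty_dental_area",
                   "normalization requires non-empty dental masks")
  nr / nc
}

#' Measure one image of a moment, absolute and relative to the reference
#'
#' Computes the full measurement record for a single image: per-class
#' pixel counts and area percentages, mean visible G-B intensity, the API
#' index, and — when an elapsed time is given — growth and area-time
#' indices for visible plaque and for total plaque (visible + both
#' non-visible levels), all measured against the reference moment.
#'
#' @param labels,gb \code{region_labels} and \code{\link{gb_map}} of the
#'   current image.
#' @param ref_labels,ref_gb The same for the paired reference-moment
#'   image; \code{NULL} when the current image \emph{is} the reference
#'   (relative fields are then \code{NA}).
#' @param elapsed_hours Hours since the reference moment (\code{NA} or 0
#'   for the reference itself).
#' @return One-row \code{data.frame} with columns \code{dental_pixels},
#'   \code{<class>_pixels}, \code{<class>_percent},
#'   \code{mean_visible_intensity}, \code{api_index},
#'   \code{growth_index_visible}, \code{growth_index_total},
#'   \code{area_time_visible}, \code{area_time_total},
#'   \code{elapsed_hours}, \code{delta_used}, \code{l_used},
#'   \code{normalization_factor}.
#' @export
measure_moment <- function(labels, gb, ref_labels = NULL, ref_gb = NULL,
                           elapsed_hours = NA_real_) {
  cc <- class_counts(labels)
  dental <- sum(cc[c("VISIBLE", "NV1", "NV2", "NONPLAQUE")])
  if (dental == 0)
    plaquant_error("plaquant_empty_dental_area", "no dental pixels to measure")
  pct <- 100 * cc[c("VISIBLE", "NV1", "NV2", "NONPLAQUE")] / dental
  vis_sel <- labels$labels == .CLASS_CODES[["VISIBLE"]]
  mean_vis <- if (any(vis_sel)) mean(gb[vis_sel]) else NA_real_

  rel <- list(growth_index_visible = NA_real_, growth_index_total = NA_real_,
              area_time_visible = NA_real_, area_time_total = NA_real_,
              normalization_factor = NA_real_)
  if (!is.null(ref_labels) && !is.na(elapsed_hours) && elapsed_hours > 0) {
    ref_pct_vis <- area_percent(ref_labels, "VISIBLE")
    ref_pct_tot <- ref_pct_vis + area_percent(ref_labels, "NV1") +
      area_percent(ref_labels, "NV2")
    pct_tot <- sum(pct[c("VISIBLE", "NV1", "NV2")])
    rel$growth_index_visible <-
      area_growth_index(pct[["VISIBLE"]], ref_pct_vis, elapsed_hours)
    rel$growth_index_total <-
      area_growth_index(pct_tot, ref_pct_tot, elapsed_hours)
    rel$area_time_visible <-
      area_time_index(pct[["VISIBLE"]], rel$growth_index_visible)
    rel$area_time_total <-
      area_time_index(pct_tot, rel$growth_index_total)
    rel$normalization_factor <-
      normalization_factor(labels$labels != .CLASS_CODES[["OUTSIDE"]],
                           ref_labels$labels != .CLASS_CODES[["OUTSIDE"]])
  }

  data.frame(
    dental_pixels = dental,
    visible_pixels = cc[["VISIBLE"]], nv1_pixels = cc[["NV1"]],
    nv2_pixels = cc[["NV2"]], nonplaque_pixels = cc[["NONPLAQUE"]],
    visible_percent = pct[["VISIBLE"]], nv1_percent = pct[["NV1"]],
    nv2_percent = pct[["NV2"]], nonplaque_percent = pct[["NONPLAQUE"]],
    mean_visible_intensity = mean_vis,
    api_index = api_index(labels, gb),
    elapsed_hours = elapsed_hours,
    growth_index_visible = rel$growth_index_visible,
    growth_index_total = rel$growth_index_total,
    area_time_visible = rel$area_time_visible,
    area_time_total = rel$area_time_total,
    delta_used = labels$delta_used,
    l_used = labels$l_used,
    normalization_factor = rel$normalization_factor,
    row.names = NULL
  )
}
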