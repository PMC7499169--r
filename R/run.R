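#' Process a single UV image through the full pipeline
#'
#' Segments the dental area, computes the G-B map, resolves the delta and
#' l thresholds (delta from the image itself when set to \code{"auto"}; l
#' from the reference comparison, falling back to delta when no reference
#' is given or the histograms never cross) and classifies every dental
#' pixel.
#'
#' @param image A \code{\link{uv_image}}.
#' @param params A \code{\link{processing_params}}.
#' @param reference Optional result of \code{process_image} for the
#'   paired reference image; \code{NULL} when processing the reference
#'   itself.
#' @return List with \code{mask} (\code{dental_mask}), \code{gb}
#'   (\code{gb_map}), \code{labels} (\code{region_labels}),
#'   \code{nv_hist} (\code{gb_histogram} of the non-visible first
#'   approximation), \code{delta}, \code{l} and \code{l_fallback}.
#' @export
process_image <- function(image, params = processing_params(), reference = NULL) {
  stopifnot(inherits(image, "uv_image"))
  image <- downscale_to_bytes(image, params$max_image_bytes)
  mask <- segment_dental_area(image, params)
  cropped <- crop_image(image, params$crop)
  gb <- gb_map(cropped, mask)
  delta <- if (identical(params$delta, "auto")) auto_delta(cropped, mask)
           else params$delta
  nv_hist <- nonvisible_histogram(cropped, mask)
  if (is.null(reference)) {
    l <- delta; fallback <- TRUE
  } else {
    l <- auto_l(nv_hist, reference$nv_hist, delta)
    fallback <- attr(l, "fallback")
  }
  labels <- classify_plaque(gb, cropped, delta, as.numeric(l))
  list(mask = mask, gb = gb, labels = labels, nv_hist = nv_hist,
       delta = delta, l = as.numeric(l), l_fallback = isTRUE(fallback))
}

#' Run a plaque experiment
#'
#' Processes every moment of every patient in an experiment: the
#' reference moment of each patient is processed first, then each later
#' moment is classified and measured against it. Image \code{k} of a
#' moment is paired with image \code{k} of the reference moment when it
#' exists, otherwise with the reference's frontal (first) image.
#'
#' Processing failures confined to one image (unreadable file, empty
#' dental area) are recorded in the manifest and skip only that image; a
#' missing reference moment is a configuration error and aborts the run.
#'
#' @param config Path to a YAML/JSON experiment configuration (see
#'   \code{\link{read_experiment_config}}) or a
#'   \code{\link{plaque_experiment}} object.
#' @param out_dir Optional output directory. When given, the run writes
#'   per image a dental-mask PNG, a labeled PNG (green visible plaque,
#'   red/orange non-visible levels, blue non-plaque), the G-B histogram
#'   as CSV and PNG, plus pie/bar class charts per moment, a combined
#'   \code{measurements.csv} and a \code{manifest.json}.
#' @return An object of class \code{plaque_run}: list with
#'   \code{measurements} (data frame, one row per image per moment),
#'   \code{manifest} and \code{out_dir}.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' cfg <- write_synthetic_experiment(dir, scene_spec(seed = 7),
#'   rate = 0.75,
#'   timestamps = as.POSIXct("2020-03-02 09:00:00", tz = "UTC") +
#'     c(0, 48, 96) * 3600)
#' run <- run_experiment(cfg, out_dir = file.path(dir, "out"))
#' summary(run)
#' }
#' @export
run_experiment <- function(config, out_dir = NULL) {
  exp <- if (inherits(config, "plaque_experiment")) config
         else read_experiment_config(config)
  validate_experiment(exp)
  params <- exp$params
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); resolved <- list(); failures <- list()
  pids <- unique(vapply(exp$moments, `[[`, character(1), "patient_id"))

  for (pid in pids) {
    ms <- Filter(function(m) m$patient_id == pid, exp$moments)
    ord <- order(!vapply(ms, `[[`, logical(1), "is_reference"),
                 vapply(ms, function(m) as.numeric(m$timestamp), numeric(1)))
    ms <- ms[ord]
    t0 <- ms[[1]]$timestamp
    ref_results <- list()

    for (mi in seq_along(ms)) {
      m <- ms[[mi]]
      is_ref <- m$is_reference
      elapsed <- as.numeric(difftime(m$timestamp, t0, units = "hours"))
      mdir <- if (!is.null(out_dir))
        file.path(out_dir, pid, if (nzchar(m$label)) m$label else sprintf("moment%02d", mi))
      if (!is.null(out_dir)) dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      moment_pcts <- NULL

      for (k in seq_along(m$images)) {
        src <- m$images[[k]]
        img_name <- if (is.character(src)) src else sprintf("<in-memory image %d>", k)
        res <- tryCatch({
          img <- if (is.character(src))
            read_uv_image(src, timestamp = m$timestamp,
                          max_bytes = params$max_image_bytes)
          else src
          p <- params
          if (!is.null(m$crop)) p$crop <- m$crop
          ref <- if (is_ref) NULL
                 else if (length(ref_results) == 0) NULL
                 else ref_results[[min(k, length(ref_results))]]
          if (!is_ref && is.null(ref))
            plaquant_error("plaquant_config_error",
                           sprintf("no processed reference image for patient %s", pid))
          pr <- process_image(img, p, reference = ref)
          meas <- measure_moment(pr$labels, pr$gb,
                                 ref_labels = if (is_ref) NULL else ref$labels,
                                 ref_gb = if (is_ref) NULL else ref$gb,
                                 elapsed_hours = if (is_ref) NA_real_ else elapsed)
          list(pr = pr, meas = meas)
        }, plaquant_error = function(e) e)

        if (inherits(res, "plaquant_error")) {
          if (inherits(res, "plaquant_config_error")) stop(res)
          failures[[length(failures) + 1]] <- list(
            patient = pid, moment = m$label, image = img_name,
            error = class(res)[1], message = conditionMessage(res))
          next
        }
        if (is_ref) ref_results[[k]] <- res$pr

        row <- cbind(data.frame(patient_id = pid, moment_label = m$label,
                                timestamp = format(m$timestamp, "%Y-%m-%dT%H:%M:%S"),
                                is_reference = is_ref, image_index = k,
                                image = img_name, stringsAsFactors = FALSE),
                     res$meas)
        rows[[length(rows) + 1]] <- row
        resolved[[length(resolved) + 1]] <- list(
          patient = pid, moment = m$label, image = img_name,
          delta = res$pr$delta, l = res$pr$l, l_fallback = res$pr$l_fallback,
          threshold = as.numeric(attr(res$pr$mask, "threshold")))
        moment_pcts <- res$meas[1, c("visible_percent", "nv1_percent",
                                     "nv2_percent", "nonplaque_percent")]

        if (!is.null(out_dir)) {
          stem <- file.path(mdir, sprintf("image%02d", k))
          write_mask_png(res$pr$mask$mask, paste0(stem, "_dental_mask.png"))
          write_rgb_png(label_image(res$pr$labels), paste0(stem, "_labels.png"))
          write_gb_histogram_csv(gb_histogram(res$pr$gb), paste0(stem, "_histogram.csv"))
          grDevices::png(paste0(stem, "_histogram.png"), width = 700, height = 480)
          plot_gb_histogram(gb_histogram(res$pr$gb),
                            reference = if (!is_ref && !is.null(ref_results[[min(k, length(ref_results))]]))
                              gb_histogram(ref_results[[min(k, length(ref_results))]]$gb),
                            main = sprintf("%s %s image %d", pid, m$label, k))
          dev.off()
        }
      }
      if (!is_ref && length(ref_results) == 0)
        plaquant_error("plaquant_config_error",
                       sprintf("reference moment of patient %s produced no usable image", pid))
      if (!is.null(out_dir) && !is.null(moment_pcts)) {
        grDevices::png(file.path(mdir, "class_charts.png"), width = 900, height = 480)
        plot_class_charts(as.numeric(moment_pcts),
                          main = sprintf("%s %s", pid, m$label))
        dev.off()
      }
    }
  }

  measurements <- if (length(rows)) do.call(rbind, rows) else data.frame()
  manifest <- list(
    experiment = exp$name,
    software = paste("plaquant", as.character(packageVersion("plaquant"))),
    params = unclass(params)[!vapply(unclass(params), is.null, logical(1))],
    resolved_parameters = resolved,
    failures = failures,
    n_measurements = nrow(measurements))
  if (!is.null(out_dir)) {
    write.csv(measurements, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(measurements = measurements, manifest = manifest,
                 out_dir = out_dir),
            class = "plaque_run")
}

# pie + bar chart of the four class percentages
plot_class_charts <- function(pcts, main = "") {
  nm <- c("visible", "NV1", "NV2", "non-plaque")
  cols <- c("green3", "red2", "orange", "royalblue")
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  keep <- pcts > 0
  if (any(keep)) pie(pcts[keep], labels = sprintf("%s %.1f%%", nm[keep], pcts[keep]),
                     col = cols[keep], main = main)
  barplot(pcts, names.arg = nm, col = cols, ylab = "% of dental area",
          ylim = c(0, 100))
  invisible(pcts)
}

#' @export
print.plaque_run <- function(x, ...) {
  cat(sprintf("Plaque experiment run: %d measurement row(s), %d failure(s)\n",
              nrow(x$measurements), length(x$manifest$failures)))
  if (!is.null(x$out_dir)) cat(sprintf("  outputs in: %s\n", x$out_dir))
  invisible(x)
}

#' @export
summary.plaque_run <- function(object, ...) {
  m <- object$measurements
  if (nrow(m) == 0) { cat("empty run\n"); return(invisible(object)) }
  cat(sprintf("Plaque measurements (%d image(s), %d patient(s)):\n\n",
              nrow(m), length(unique(m$patient_id))))
  show <- m[, c("patient_id", "moment_label", "elapsed_hours",
                "visible_percent", "nv1_percent", "nv2_percent",
                "api_index", "growth_index_visible", "area_time_visible")]
  print(format(show, digits = 4), row.names = FALSE)
  invisible(object)
}

#' @export
plot.plaque_run <- function(x, patient = NULL, ...) {
  m <- x$measurements
  if (nrow(m) == 0) return(invisible(x))
  if (is.null(patient)) patient <- m$patient_id[1]
  m <- m[m$patient_id == patient & m$image_index == 1, ]
  mat <- t(as.matrix(m[, c("visible_percent", "nv1_percent",
                           "nv2_percent", "nonplaque_percent")]))
  barplot(mat, beside = TRUE, names.arg = m$moment_label,
          col = c("green3", "red2", "orange", "royalblue"),
          ylab = "% of dental area",
          main = sprintf("patient %s: class areas by moment", patient),
          legend.text = c("visible", "NV1", "NV2", "non-plaque"),
          args.legend = list(x = "topright", bty = "n"))
  invisible(x)
}
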