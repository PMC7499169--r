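#' Synthetic UV dentition scene specification
#'
#' Describes a synthetic fluorescein/UV scene: a dark background, a band
#' of reddish gingiva, bright blue elliptical teeth, green plaque patches
#' with a controllable G-B distribution, and optional near-white specular
#' artifacts. Rendering is fully deterministic for a fixed seed.
#'
#' Default intensities emulate the contrast structure of real disclosed
#' images: clean enamel is blue-dominated (B around 200, G-B around -60),
#' plaque is green-dominated (G-B around +60), gingiva is a dim reddish
#' band whose B+R sum sits well below the enamel's, and the background is
#' near black. Teeth cover roughly a quarter of the canvas so that the
#' default 75% darkest-pixel threshold separates enamel from everything
#' else.
#'
#' @param height,width Canvas size in pixels.
#' @param teeth List of tooth blobs, each a list with \code{center}
#'   (row, col), \code{radii} (row, col semi-axes), \code{blue_mean},
#'   \code{blue_sd}. \code{NULL} uses a default row of four teeth scaled
#'   to the canvas.
#' @param plaque List of plaque patches, each a list with \code{tooth}
#'   (index into \code{teeth}), \code{coverage} (fraction of that tooth's
#'   area), \code{gb_mean}, \code{gb_sd} (G-B distribution of the patch).
#' @param tooth_gb_mean,tooth_gb_sd G-B distribution of clean (non-plaque)
#'   enamel pixels; the mean must be negative.
#' @param gingiva List with \code{rows} (number of gingiva rows at the top
#'   of the canvas) and channel means \code{red_mean}, \code{green_mean},
#'   \code{blue_mean}; \code{NULL} disables the band.
#' @param artifacts List of near-white discs, each a list with
#'   \code{center}, \code{radius}, \code{value} (intensity for all three
#'   channels).
#' @param noise_sd Per-pixel Gaussian noise, intensity units.
#' @param background_mean Background channel mean.
#' @param seed Integer seed; identical seeds give bit-identical renders.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(height = 240, width = 360,
                       teeth = NULL,
                       plaque = list(list(tooth = 1, coverage = 0.2,
                                          gb_mean = 60, gb_sd = 8),
                                     list(tooth = 3, coverage = 0.2,
                                          gb_mean = 60, gb_sd = 8)),
                       tooth_gb_mean = -60, tooth_gb_sd = 8,
                       gingiva = list(rows = round(height * 0.25),
                                      red_mean = 90, green_mean = 40,
                                      blue_mean = 15),
                       artifacts = list(),
                       noise_sd = 4, background_mean = 8,
                       seed = 1) {
  if (is.null(teeth)) teeth <- default_teeth(height, width)
  stopifnot(height >= 1, width >= 1, noise_sd >= 0, tooth_gb_mean < 0)
  for (p in plaque)
    stopifnot(p$tooth >= 1, p$tooth <= length(teeth),
              p$coverage >= 0, p$coverage <= 1)
  structure(
    list(height = height, width = width, teeth = teeth, plaque = plaque,
         tooth_gb_mean = tooth_gb_mean, tooth_gb_sd = tooth_gb_sd,
         gingiva = gingiva, artifacts = artifacts,
         noise_sd = noise_sd, background_mean = background_mean,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# four teeth in a row, sized so the dentition covers ~23% of the canvas
default_teeth <- function(height, width) {
  ry <- round(height * 0.19); rx <- round(width * 0.097)
  cr <- round(height * 0.58)
  lapply(seq(0.167, by = 0.222, length.out = 4), function(f)
    list(center = c(cr, round(width * f)), radii = c(ry, rx),
         blue_mean = 200, blue_sd = 8))
}

# run code with a locally-seeded RNG, leaving global state untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(height, width, center, radii) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

disc_mask <- function(height, width, center, radius) {
  ellipse_mask(height, width, center, c(radius, radius))
}

#' Render a synthetic scene
#'
#' Produces a UV-like dentition image plus ground-truth masks. Tooth
#' pixels have B well above G; plaque pixels have G above B by the
#' programmed margin; plaque patches are spatially coherent blobs grown
#' from an anchor point inside their tooth (the \code{coverage} fraction
#' of the tooth's pixels nearest the anchor), so their shape and area are
#' exact by construction.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @param timestamp Optional timestamp stored on the image.
#' @return List with \code{image} (a \code{\link{uv_image}}),
#'   \code{dental_truth} and \code{plaque_truth} (logical matrices,
#'   \code{plaque_truth} a subset of \code{dental_truth}).
#' @export
render_scene <- function(spec, timestamp = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  with_local_seed(spec$seed, {
    r <- matrix(rnorm(h * w, spec$background_mean, spec$noise_sd), h, w)
    g <- matrix(rnorm(h * w, spec$background_mean, spec$noise_sd), h, w)
    b <- matrix(rnorm(h * w, spec$background_mean, spec$noise_sd), h, w)

    if (!is.null(spec$gingiva) && spec$gingiva$rows > 0) {
      rows <- seq_len(min(spec$gingiva$rows, h))
      n <- length(rows) * w
      r[rows, ] <- rnorm(n, spec$gingiva$red_mean, spec$noise_sd)
      g[rows, ] <- rnorm(n, spec$gingiva$green_mean, spec$noise_sd)
      b[rows, ] <- rnorm(n, spec$gingiva$blue_mean, spec$noise_sd)
    }

    dental <- matrix(FALSE, h, w)
    tooth_masks <- vector("list", length(spec$teeth))
    for (i in seq_along(spec$teeth)) {
      t <- spec$teeth[[i]]
      tm <- ellipse_mask(h, w, t$center, t$radii)
      tooth_masks[[i]] <- tm
      n <- sum(tm)
      if (n == 0) next
      bt <- rnorm(n, t$blue_mean, t$blue_sd)
      b[tm] <- bt
      g[tm] <- bt + rnorm(n, spec$tooth_gb_mean, spec$tooth_gb_sd)
      r[tm] <- rnorm(n, 25, spec$noise_sd)
      dental <- dental | tm
    }

    plaque <- matrix(FALSE, h, w)
    for (p in spec$plaque) {
      tm <- tooth_masks[[p$tooth]]
      n <- sum(tm)
      if (n == 0 || p$coverage <= 0) next
      idx <- which(tm, arr.ind = TRUE)
      ctr <- spec$teeth[[p$tooth]]$center
      # anchor displaced from the tooth center; patch = nearest pixels
      ang <- runif(1, 0, 2 * pi)
      anchor <- ctr + 0.5 * spec$teeth[[p$tooth]]$radii * c(sin(ang), cos(ang))
      d2 <- (idx[, 1] - anchor[1])^2 + (idx[, 2] - anchor[2])^2
      take <- idx[order(d2)[seq_len(round(p$coverage * n))], , drop = FALSE]
      pm <- matrix(FALSE, h, w)
      pm[take] <- TRUE
      g[pm] <- b[pm] + rnorm(sum(pm), p$gb_mean, p$gb_sd)
      plaque <- plaque | pm
    }

    for (a in spec$artifacts) {
      am <- disc_mask(h, w, a$center, a$radius)
      r[am] <- a$value; g[am] <- a$value; b[am] <- a$value
    }

    px <- array(0L, dim = c(h, w, 3))
    px[, , 1] <- clip8(r); px[, , 2] <- clip8(g); px[, , 3] <- clip8(b)
    list(image = uv_image(px, timestamp = timestamp),
         dental_truth = dental,
         plaque_truth = plaque)
  })
}

clip8 <- function(x) as.integer(round(pmin(255, pmax(0, x))))

#' Render a longitudinal series of synthetic moments
#'
#' Emulates a plaque-regrowth experiment: the first timestamp is the
#' reference moment with zero plaque coverage; at each later moment every
#' tooth carries a plaque patch covering \code{rate * hours_elapsed}
#' percent of its area (capped at 100), so the visible plaque percentage
#' of the whole dental area grows linearly at \code{rate} percent per
#' hour. The G-B mean of clean enamel also drifts mildly upward over
#' time, reproducing the gradual flattening of real G-B histograms as
#' plaque matures.
#'
#' @param spec Base \code{\link{scene_spec}}; its \code{plaque} list is
#'   replaced per moment.
#' @param rate Programmed visible-area growth, percent of dental area per
#'   hour.
#' @param timestamps Increasing \code{POSIXct} (or parseable) vector;
#'   first entry is the reference moment.
#' @param gb_drift_per_hour Upward drift of the clean-enamel G-B mean,
#'   intensity units per hour. Default 0.05.
#' @param patient_id Patient identifier attached to the moments.
#' @return List of per-moment entries, each with \code{moment} (a
#'   \code{\link{plaque_moment}} holding the rendered image),
#'   \code{dental_truth}, \code{plaque_truth} and \code{coverage} (the
#'   programmed visible percentage).
#' @export
render_series <- function(spec, rate, timestamps,
                          gb_drift_per_hour = 0.05, patient_id = "synthetic") {
  stopifnot(inherits(spec, "scene_spec"), rate >= 0, length(timestamps) >= 1)
  ts <- lapply(timestamps, parse_timestamp)
  hours <- vapply(ts, function(t)
    as.numeric(difftime(t, ts[[1]], units = "hours")), numeric(1))
  if (any(diff(hours) <= 0))
    plaquant_error("plaquant_config_error", "timestamps must be strictly increasing")
  lapply(seq_along(ts), function(i) {
    cov <- min(100, rate * hours[i]) / 100
    sp <- spec
    sp$seed <- (spec$seed * 131L + i) %% 2147483647L
    sp$tooth_gb_mean <- min(-1, spec$tooth_gb_mean + gb_drift_per_hour * hours[i])
    sp$plaque <- if (cov > 0)
      lapply(seq_along(spec$teeth), function(k)
        list(tooth = k, coverage = cov, gb_mean = 60, gb_sd = 8))
    else list()
    sc <- render_scene(sp, timestamp = ts[[i]])
    list(moment = plaque_moment(patient_id = patient_id,
                                timestamp = ts[[i]],
                                images = list(sc$image),
                                is_reference = (i == 1L),
                                label = sprintf("M%d", i - 1L)),
         dental_truth = sc$dental_truth,
         plaque_truth = sc$plaque_truth,
         coverage = 100 * cov)
  })
}

#' Write a complete synthetic experiment to disk
#'
#' Renders a longitudinal series, writes each moment's image as PNG and a
#' matching experiment configuration YAML, immediately consumable by
#' \code{\link{run_experiment}}.
#'
#' @param dir Output directory (created if needed).
#' @param spec A \code{\link{scene_spec}}.
#' @param rate Programmed growth rate, percent area per hour.
#' @param timestamps Moment timestamps; first is the reference.
#' @param params \code{\link{processing_params}} to embed in the config.
#' @param patient_id Patient identifier.
#' @return Path to the written config YAML, invisibly; ground truths are
#'   returned as attribute \code{"truth"}.
#' @export
write_synthetic_experiment <- function(dir, spec = scene_spec(),
                                       rate = 0.75,
                                       timestamps = seq(
                                         as.POSIXct("2020-03-02 09:00:00", tz = "UTC"),
                                         by = 24 * 3600, length.out = 5),
                                       params = processing_params(),
                                       patient_id = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- render_series(spec, rate, timestamps, patient_id = patient_id)
  moments <- list()
  for (i in seq_along(series)) {
    fn <- sprintf("%s_m%d.png", patient_id, i - 1L)
    write_rgb_png(series[[i]]$moment$images[[1]]$pixels, file.path(dir, fn))
    moments[[i]] <- list(
      label = series[[i]]$moment$label,
      timestamp = format(series[[i]]$moment$timestamp, "%Y-%m-%dT%H:%M:%S"),
      is_reference = series[[i]]$moment$is_reference,
      images = list(fn)
    )
  }
  cfg <- list(
    name = "synthetic plaque regrowth experiment",
    params = unclass(params)[!vapply(unclass(params), is.null, logical(1))],
    patients = list(list(id = patient_id, moments = moments))
  )
  path <- file.path(dir, "experiment.yaml")
  yaml::write_yaml(cfg, path)
  invisible(structure(path, truth = lapply(series, function(s)
    s[c("dental_truth", "plaque_truth", "coverage")])))
}
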