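#' Construct a plaque moment
#'
#' A plaque moment is the set of images (a frontal view, optionally
#' lateral views) captured from one patient at one timepoint. One moment
#' per patient is the designated \emph{reference moment} ("moment 0"),
#' usually taken after professional dental cleaning; all growth indices
#' are measured against it.
#'
#' @param patient_id Opaque patient identifier.
#' @param timestamp Acquisition time (\code{POSIXct} or parseable string).
#' @param images Non-empty list: \code{\link{uv_image}} objects or file
#'   paths (loaded lazily at processing time). The frontal view comes
#'   first.
#' @param is_reference Whether this is the patient's reference moment.
#' @param label Free-text label (e.g. \code{"M0"}, \code{"24h"}).
#' @param crop Optional crop rectangle applied to all images of this
#'   moment (see \code{\link{processing_params}}).
#' @return An object of class \code{plaque_moment}.
#' @export
plaque_moment <- function(patient_id, timestamp, images,
                          is_reference = FALSE, label = "", crop = NULL) {
  if (length(images) == 0)
    plaquant_error("plaquant_validation_error",
                   "a plaque moment needs at least one image")
  if (is.character(images)) images <- as.list(images)
  ts <- parse_timestamp(timestamp)
  if (is.null(ts))
    plaquant_error("plaquant_validation_error", "a plaque moment needs a timestamp")
  structure(
    list(patient_id = as.character(patient_id), timestamp = ts,
         images = images, is_reference = isTRUE(is_reference),
         label = label, crop = crop),
    class = "plaque_moment"
  )
}

#' @export
print.plaque_moment <- function(x, ...) {
  cat(sprintf("Plaque moment%s '%s' of patient %s at %s (%d image%s)\n",
              if (x$is_reference) " [reference]" else "", x$label,
              x$patient_id, format(x$timestamp, "%Y-%m-%d %H:%M"),
              length(x$images), if (length(x$images) > 1) "s" else ""))
  invisible(x)
}

#' Create an empty plaque experiment
#'
#' An experiment groups the plaque moments selected for processing plus
#' one set of processing parameters. Moments are added with
#' \code{\link{attach_moment}}.
#'
#' @param params A \code{\link{processing_params}} object.
#' @param name Experiment name.
#' @return An object of class \code{plaque_experiment}.
#' @export
plaque_experiment <- function(params = processing_params(), name = "experiment") {
  stopifnot(inherits(params, "processing_params"))
  structure(list(name = name, params = params, moments = list()),
            class = "plaque_experiment")
}

#' Attach a moment to an experiment
#'
#' Adds a plaque moment; at most one reference moment per patient is
#' allowed. When a non-reference moment is attached and the experiment
#' does not yet hold that patient's reference, the reference is looked up
#' in \code{patient_db} (a list of \code{\link{plaque_moment}}s acting as
#' the patient record pool) and attached automatically, mirroring the
#' rule that selecting any moment always brings its moment 0 along.
#'
#' @param experiment A \code{\link{plaque_experiment}}.
#' @param moment A \code{\link{plaque_moment}}.
#' @param patient_db Optional list of \code{plaque_moment}s to resolve
#'   missing reference moments from.
#' @return The updated experiment.
#' @export
attach_moment <- function(experiment, moment, patient_db = NULL) {
  stopifnot(inherits(experiment, "plaque_experiment"),
            inherits(moment, "plaque_moment"))
  if (moment$is_reference) {
    for (m in experiment$moments)
      if (m$patient_id == moment$patient_id && m$is_reference)
        plaquant_error("plaquant_validation_error",
                       sprintf("patient %s already has a reference moment",
                               moment$patient_id))
  } else {
    has_ref <- any(vapply(experiment$moments, function(m)
      m$patient_id == moment$patient_id && m$is_reference, logical(1)))
    if (!has_ref && !is.null(patient_db)) {
      for (m in patient_db)
        if (inherits(m, "plaque_moment") &&
            m$patient_id == moment$patient_id && m$is_reference) {
          experiment <- attach_moment(experiment, m)
          break
        }
    }
  }
  experiment$moments <- c(experiment$moments, list(moment))
  experiment
}

#' Validate an experiment
#'
#' Checks that every patient with attached moments has exactly one
#' reference moment and that no non-reference moment predates it.
#'
#' @param experiment A \code{\link{plaque_experiment}}.
#' @return \code{TRUE}, invisibly; otherwise a configuration or
#'   validation error is raised.
#' @export
validate_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "plaque_experiment"))
  pids <- unique(vapply(experiment$moments, `[[`, character(1), "patient_id"))
  for (pid in pids) {
    ms <- Filter(function(m) m$patient_id == pid, experiment$moments)
    refs <- Filter(function(m) m$is_reference, ms)
    if (length(refs) == 0)
      plaquant_error("plaquant_config_error",
                     sprintf("patient %s has no reference moment", pid))
    if (length(refs) > 1)
      plaquant_error("plaquant_validation_error",
                     sprintf("patient %s has %d reference moments", pid, length(refs)))
    t0 <- refs[[1]]$timestamp
    for (m in ms)
      if (!m$is_reference && m$timestamp < t0)
        plaquant_error("plaquant_validation_error",
                       sprintf("moment '%s' of patient %s predates the reference moment",
                               m$label, pid))
  }
  invisible(TRUE)
}

#' @export
print.plaque_experiment <- function(x, ...) {
  pids <- unique(vapply(x$moments, `[[`, character(1), "patient_id"))
  cat(sprintf("Plaque experiment '%s': %d moment(s), %d patient(s)\n",
              x$name, length(x$moments), length(pids)))
  invisible(x)
}

# config I/O -------------------------------------------------------------

#' Read an experiment configuration
#'
#' Loads a YAML (or JSON) experiment description: a \code{params} block
#' (any subset of \code{\link{processing_params}} fields) and a
#' \code{patients} list, each with an \code{id} and \code{moments}
#' carrying \code{label}, ISO-8601 \code{timestamp}, \code{is_reference},
#' \code{images} (paths relative to the config file) and optional
#' \code{crop}.
#'
#' @param path Config file path.
#' @return A \code{\link{plaque_experiment}} with image paths resolved
#'   relative to the config location.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path))
    plaquant_error("plaquant_io_error", paste0("config not found: ", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pargs <- cfg$params
  if (!is.null(pargs$crop)) pargs$crop <- as.integer(unlist(pargs$crop))
  params <- do.call(processing_params, if (is.null(pargs)) list() else pargs)
  exp <- plaque_experiment(params, name = if (is.null(cfg$name)) "experiment" else cfg$name)
  if (is.null(cfg$patients) || length(cfg$patients) == 0)
    plaquant_error("plaquant_config_error", "config lists no patients")
  for (p in cfg$patients) {
    if (is.null(p$id))
      plaquant_error("plaquant_config_error", "every patient needs an id")
    for (m in p$moments) {
      imgs <- vapply(m$images, function(f)
        if (grepl("^/", f)) f else file.path(base, f), character(1))
      exp <- attach_moment(exp, plaque_moment(
        patient_id = p$id, timestamp = m$timestamp,
        images = as.list(imgs),
        is_reference = isTRUE(m$is_reference),
        label = if (is.null(m$label)) "" else m$label,
        crop = if (is.null(m$crop)) NULL else as.integer(unlist(m$crop))))
    }
  }
  validate_experiment(exp)
  exp
}

#' Write an experiment configuration
#'
#' Serializes an experiment (moments with image paths plus the parameter
#' block) to YAML; reloading with \code{\link{read_experiment_config}}
#' and reprocessing the same images reproduces identical measurements.
#'
#' @param experiment A \code{\link{plaque_experiment}} whose moment
#'   images are file paths.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_experiment_config <- function(experiment, path) {
  stopifnot(inherits(experiment, "plaque_experiment"))
  pids <- unique(vapply(experiment$moments, `[[`, character(1), "patient_id"))
  patients <- lapply(pids, function(pid) {
    ms <- Filter(function(m) m$patient_id == pid, experiment$moments)
    list(id = pid, moments = lapply(ms, function(m) {
      if (!all(vapply(m$images, is.character, logical(1))))
        plaquant_error("plaquant_config_error",
                       "only path-backed moments can be serialized")
      out <- list(label = m$label,
                  timestamp = format(m$timestamp, "%Y-%m-%dT%H:%M:%S"),
                  is_reference = m$is_reference,
                  images = m$images)
      if (!is.null(m$crop)) out$crop <- as.integer(m$crop)
      out
    }))
  })
  p <- unclass(experiment$params)
  yaml::write_yaml(list(name = experiment$name,
                        params = p[!vapply(p, is.null, logical(1))],
                        patients = patients), path)
  invisible(path)
}
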