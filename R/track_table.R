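# Track-table and configuration I/O.

#' Write track tables to CSV
#'
#' Writes two CSVs: a detail table with one row per focus (`track_id`,
#' `frame`, `x_px`, `y_px`, `intensity_photons`, `snr`, `sigma_x_px`,
#' `sigma_y_px`) and a per-track summary (`track_id`, `n_foci`,
#' `initial_intensity`, `stoichiometry`, `diffusivity`, `mean_snr`).
#' Coordinates are 0-based; full numeric precision is preserved.
#'
#' @param linked foci data.frame with `track_id`.
#' @param path detail CSV path; the summary goes to
#'   `sub("\\.csv$", "_summary.csv", path)`.
#' @param summary optional precomputed summary data.frame with the columns
#'   above; when `NULL`, derived fields absent from `linked` are written as
#'   `NA`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_track_table <- function(linked, path, summary = NULL) {
  detail <- data.frame(
    track_id = linked$track_id, frame = linked$frame,
    x_px = linked$x, y_px = linked$y,
    intensity_photons = linked$intensity, snr = linked$snr,
    sigma_x_px = linked$sigma_x, sigma_y_px = linked$sigma_y)
  if (is.null(summary)) {
    base <- track_summary(linked)
    nr <- nrow(base)
    summary <- data.frame(track_id = base$track_id, n_foci = base$n_foci,
                          initial_intensity = rep(NA_real_, nr),
                          stoichiometry = rep(NA_real_, nr),
                          diffusivity = rep(NA_real_, nr),
                          mean_snr = base$mean_snr)
  }
  spath <- sub("\\.csv$", "_summary.csv", path)
  if (identical(spath, path)) spath <- paste0(path, "_summary.csv")
  ok <- try({
    utils::write.csv(format(detail, digits = 17, trim = TRUE, nsmall = 0,
                            scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    utils::write.csv(format(summary, digits = 17, trim = TRUE, nsmall = 0,
                            scientific = FALSE),
                     spath, row.names = FALSE, quote = FALSE)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write '", path, "'")
  invisible(c(detail = path, summary = spath))
}

#' Read a track detail table written by [write_track_table()]
#'
#' @param path detail CSV path.
#' @return Foci data.frame with package-internal column names.
#' @export
read_track_table <- function(path) {
  raw <- utils::read.csv(path)
  if (nrow(raw) == 0L) {
    out <- empty_foci(); out$track_id <- integer(0)
    return(out)
  }
  data.frame(track_id = as.integer(raw$track_id),
             frame = as.integer(raw$frame),
             x = raw$x_px, y = raw$y_px,
             intensity = raw$intensity_photons, snr = raw$snr,
             sigma_x = raw$sigma_x_px, sigma_y = raw$sigma_y_px)
}

#' Read an analysis configuration file
#'
#' YAML configuration holding the camera model, detection/sifting
#' parameters, and the channel pattern. Missing fields fall back to package
#' defaults.
#'
#' @param path YAML file.
#' @return List with `camera` (a [camera_model()]), `pixel_size`,
#'   `frame_interval`, `channel_pattern`, `snr_threshold`,
#'   `min_consecutive`, `permissive_snr`, plus any extra fields verbatim.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cam <- cfg$camera %||% list()
  cfg$camera <- camera_model(gain = cam$gain %||% 0.6,
                             offset = cam$offset %||% 100,
                             read_noise = cam$read_noise %||% 1.6,
                             bit_depth = cam$bit_depth %||% 16)
  cfg$pixel_size <- cfg$pixel_size %||% 53
  cfg$frame_interval <- cfg$frame_interval %||% 10
  cfg$channel_pattern <- cfg$channel_pattern %||% "0"
  cfg$snr_threshold <- cfg$snr_threshold %||% 0.4
  cfg$min_consecutive <- cfg$min_consecutive %||% 3L
  cfg$permissive_snr <- cfg$permissive_snr %||% 0.2
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
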