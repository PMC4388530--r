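# End-to-end orchestration: PNG series -> sum-difference stack ->
# particle table -> tracks -> velocity summary, plus the optical
# geometry helpers.

#' Optical acquisition configuration
#'
#' Defaults describe the canonical setup: 40x phase contrast,
#' 1280 x 960 px camera at 30 fps, 94.2 nm pixel pitch, 30-frame
#' series (one second of video).
#'
#' @param pixel_size_nm physical pixel edge length, nm.
#' @param fps frame rate, frames/s.
#' @param frames_per_series frames per acquired series.
#' @param image_width_px,image_height_px sensor resolution.
#' @return An `optical_config`.
#' @export
optical_config <- function(pixel_size_nm = 94.2, fps = 30,
                           frames_per_series = 30,
                           image_width_px = 1280,
                           image_height_px = 960) {
  stopifnot(pixel_size_nm > 0, fps > 0, frames_per_series > 0,
            image_width_px > 0, image_height_px > 0)
  structure(list(pixel_size_nm = pixel_size_nm, fps = fps,
                 frames_per_series = frames_per_series,
                 image_width_px = image_width_px,
                 image_height_px = image_height_px),
            class = "optical_config")
}

#' Field of view in micrometres
#'
#' Image size times pixel pitch, reported to one decimal. The
#' canonical setup images a 120.6 x 90.4 um region.
#'
#' @param optics an [optical_config()].
#' @return Named numeric: `width_um`, `height_um`.
#' @export
field_of_view <- function(optics = optical_config()) {
  stopifnot(inherits(optics, "optical_config"))
  c(width_um = round(optics$image_width_px * optics$pixel_size_nm /
                       1000, 1),
    height_um = round(optics$image_height_px * optics$pixel_size_nm /
                        1000, 1))
}

#' Pipeline run configuration
#'
#' Collects every tunable of the processing chain. Parameters the
#' method itself does not fix are exposed here with conservative
#' defaults: Otsu thresholding (`threshold = NULL`), minimum particle
#' area from the 0.4 um optical detection limit, a 40 px displacement
#' gate, single-frame gap closing and a 5-detection minimum track
#' length.
#'
#' @param optics an [optical_config()].
#' @param threshold detection threshold (NULL = Otsu).
#' @param min_area minimum particle area, px^2.
#' @param weights a [feature_weights()].
#' @param gate displacement gate, px per frame interval.
#' @param max_gap maximum closable gap, frames.
#' @param min_track_len minimum detections per track.
#' @param bin_width velocity histogram bin width, um/s.
#' @return A `run_config`.
#' @export
run_config <- function(optics = optical_config(), threshold = NULL,
                       min_area = 14, weights = feature_weights(),
                       gate = 40, max_gap = 1, min_track_len = 5,
                       bin_width = 5) {
  structure(list(optics = optics, threshold = threshold,
                 min_area = min_area, weights = weights, gate = gate,
                 max_gap = max_gap, min_track_len = min_track_len,
                 bin_width = bin_width),
            class = "run_config")
}

#' Run the full tracking pipeline on a frame series
#'
#' Executes, in order: sum-difference transform with denoising and
#' normalization, particle detection and feature measurement,
#' frame-to-frame association with gap closing, and velocity
#' summarization. Per-stage counts are reported via `message()` so the
#' filtering steps remain auditable. The run is deterministic for
#' fixed inputs and configuration.
#'
#' @param input a directory containing a PNG series, or a
#'   [frame_stack()].
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, writes
#'   `tracks.csv`, `velocities.csv`, `sample_result.json` and
#'   `histogram.csv`.
#' @param dump_diff if `TRUE` and `out_dir` is set, also writes the
#'   normalized sum-difference images as PNGs (debug aid).
#' @return The [track_velocities()] `sample_result`, with the
#'   `track_set` and `particle_table` attached as attributes `tracks`
#'   and `particles`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL,
                         dump_diff = FALSE) {
  stack <- if (inherits(input, "frame_stack")) input else
    read_series(input, fps = config$optics$fps,
                pixel_size_nm = config$optics$pixel_size_nm)
  n_frames <- length(stack$frames)
  message(sprintf("loaded %d frames (%d x %d px)", n_frames,
                  ncol(stack$frames[[1]]), nrow(stack$frames[[1]])))

  diffs <- sum_difference_stack(stack)
  table <- analyze_frames(diffs, threshold = config$threshold,
                          min_area = config$min_area)
  message(sprintf("detected %d particles (mean %.1f per frame)",
                  nrow(table), nrow(table) / n_frames))

  tracks <- track_particles(table, n_frames = n_frames,
                            w = config$weights, gate = config$gate,
                            max_gap = config$max_gap,
                            min_track_len = config$min_track_len)
  n_tracks <- length(unique(tracks$tracks$track_id))
  message(sprintf("built %d tracks (%d gap frames closed)", n_tracks,
                  sum(tracks$tracks$gap)))

  optics <- optical_config(pixel_size_nm = stack$pixel_size_nm,
                           fps = stack$fps,
                           frames_per_series = n_frames,
                           image_width_px = ncol(stack$frames[[1]]),
                           image_height_px = nrow(stack$frames[[1]]))
  result <- track_velocities(tracks, optics)
  message(sprintf("%d velocity vectors, mean %.2f um/s [%s]",
                  result$n_vectors,
                  if (result$n_vectors > 0) result$mean_velocity else
                    NA,
                  result$qc_flag))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tracks$tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(result$velocities,
                     file.path(out_dir, "velocities.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mean_velocity_um_s = result$mean_velocity,
           sem_um_s = result$sem, n_vectors = result$n_vectors,
           mean_bacteria_per_image = result$mean_bacteria_per_image,
           qc_flag = result$qc_flag),
      file.path(out_dir, "sample_result.json"),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    utils::write.csv(
      velocity_histogram(result$velocities$speed_um_s,
                         config$bin_width),
      file.path(out_dir, "histogram.csv"), row.names = FALSE)
    if (dump_diff)
      for (B in diffs)
        png::writePNG(B$values / 255,
                      file.path(out_dir,
                                sprintf("diff_%04d.png",
                                        B$source_index)))
  }
  attr(result, "tracks") <- tracks
  attr(result, "particles") <- table
  result
}
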