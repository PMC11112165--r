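#' Write and read a two-channel time-lapse as multi-page TIFF
#'
#' Pages are written in (t, c, z) order as 32-bit samples. Intensities are
#' scaled into the TIFF's unit range on write; the scale factor, axis layout,
#' voxel size (um) and frame interval (s) travel in a JSON sidecar
#' (`<path>.json`), so a round trip restores the `eec_timelapse` to within
#' 32-bit quantization.
#'
#' @param timelapse An `eec_timelapse`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(timelapse, path) {
  stopifnot(inherits(timelapse, "eec_timelapse"))
  d <- dim(timelapse$data)
  lo <- min(timelapse$data)
  hi <- max(timelapse$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0L
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        k <- k + 1L
        pages[[k]] <- matrix((timelapse$data[t, ch, z, , ] - lo) / scale,
                             d[4], d[5])
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = "TCZYX",
               shape = c(d[1], d[2], d[3], d[4], d[5]),
               intensity_offset = lo, intensity_scale = scale,
               voxel_size_um = timelapse$voxel_size,
               frame_interval_s = timelapse$frame_interval)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timelapse
#' @export
read_timelapse <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$shape
  data <- array(0, dim = d)
  k <- 0L
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        k <- k + 1L
        data[t, ch, z, , ] <- pages[[k]] * meta$intensity_scale +
          meta$intensity_offset
      }
    }
  }
  new_eec_timelapse(data, meta$voxel_size_um, meta$frame_interval_s)
}

#' Write the ground truth of a simulation to CSV + JSON
#'
#' One CSV row per cell per frame (trajectory, visibility and true trace
#' values) plus a JSON sidecar of the generating configuration, making a
#' simulated data set fully self-describing on disk.
#'
#' @param sim Output of [generate_timelapse()].
#' @param cfg The generating config.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(sim, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_frame <- dplyr::left_join(sim$truth$trajectories,
                                sim$truth$traces[, c("cell", "frame", "cyto", "mito")],
                                by = c("cell", "frame"))
  per_frame <- dplyr::left_join(per_frame,
                                sim$truth$cells[, c("cell", "is_active",
                                                    "is_responder", "mito_mode")],
                                by = "cell")
  readr::write_csv(per_frame, file.path(dir, "ground_truth.csv"))
  cfg_out <- cfg
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
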