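#' Per-cell trace container
#'
#' An `eec_traces` object is a long tibble (`cell`, `frame`, `cyto`, `mito`,
#' `ratio`, and after [normalize_traces()] also `cyto_norm`, `mito_norm`,
#' `ratio_norm`) with attributes `frame_interval` (s) and `n_frames`. Frames a
#' cell was not observed in are present as `NA` rows — absent measurements are
#' marked, never interpolated.
#'
#' @param x A tibble with at least `cell`, `frame`, `cyto`, `mito`, `ratio`.
#' @param frame_interval Seconds between frames.
#' @param n_frames Recording length in frames.
#' @return The classed tibble.
#' @export
new_eec_traces <- function(x, frame_interval = 10, n_frames = NULL) {
  stopifnot(all(c("cell", "frame", "cyto", "mito", "ratio") %in% names(x)))
  attr(x, "frame_interval") <- frame_interval
  attr(x, "n_frames") <- n_frames %||%
    (if (nrow(x)) max(x$frame) + 1L else 0L)
  class(x) <- unique(c("eec_traces", class(x)))
  x
}

#' Assemble per-cell traces from tracks and object measurements
#'
#' Joins each track position to its object's channel means and completes the
#' cell-by-frame grid, so frames where a track was lost appear as `NA`
#' (absent, not interpolated). The ratio trace is mitochondrial over
#' cytoplasmic mean, per frame.
#'
#' @param tracks An `eec_tracks` from [link_objects()].
#' @param objects The object table the tracks were built from.
#' @param frame_interval Seconds between frames.
#' @return An `eec_traces` tibble.
#' @export
extract_traces <- function(tracks, objects, frame_interval = 10) {
  n_frames <- attr(tracks, "n_frames") %||% attr(objects, "n_frames")
  if (!nrow(tracks)) {
    return(new_eec_traces(
      tibble::tibble(cell = integer(), frame = integer(), cyto = numeric(),
                     mito = numeric(), ratio = numeric()),
      frame_interval, n_frames %||% 0L))
  }
  joined <- dplyr::left_join(
    dplyr::select(tracks, "track", "frame", "object"),
    dplyr::select(objects, "frame", "object", "mean_cyto", "mean_mito"),
    by = c("frame", "object"))
  if (anyNA(joined$mean_cyto)) {
    rlang::abort("track references an object missing from the object table")
  }
  out <- tibble::tibble(cell = joined$track, frame = joined$frame,
                        cyto = joined$mean_cyto, mito = joined$mean_mito)
  out <- tidyr::complete(out, cell = unique(out$cell),
                         frame = seq_len(n_frames) - 1L)
  out$ratio <- ifelse(!is.na(out$cyto) & out$cyto > 0,
                      out$mito / out$cyto, NA_real_)
  new_eec_traces(dplyr::arrange(out, .data$cell, .data$frame),
                 frame_interval, n_frames)
}

#' Normalize a trace to its first value
#'
#' `normalize_to_t0(x)[k] = x[k] / x[1]`; the first element of the result is
#' always 1. Idempotent on already-normalized traces.
#'
#' @param x Numeric vector with `x[1] > 0` (leading `NA`s are not allowed).
#' @return The normalized vector.
#' @examples
#' normalize_to_t0(c(2, 4, 6))  # 1 2 3
#' @export
normalize_to_t0 <- function(x) {
  if (length(x) == 0L) return(x)
  if (is.na(x[1]) || x[1] <= 0) {
    rlang::abort("trace value at t0 must be positive to normalize")
  }
  x / x[1]
}

#' Add t0-normalized columns to a trace table
#'
#' Divides each cell's cytoplasmic, mitochondrial and ratio trace by its
#' frame-0 value. Cells that were not observed at frame 0, or whose frame-0
#' value is not positive, cannot be normalized and are dropped with a message
#' (their ids are attached as attribute `"excluded"`).
#'
#' @param traces An `eec_traces`.
#' @return The `eec_traces` with `cyto_norm`, `mito_norm`, `ratio_norm`.
#' @export
normalize_traces <- function(traces) {
  stopifnot(inherits(traces, "eec_traces"))
  fi <- attr(traces, "frame_interval")
  nf <- attr(traces, "n_frames")
  t0 <- traces[traces$frame == 0L, c("cell", "cyto", "mito", "ratio")]
  bad <- t0$cell[is.na(t0$cyto) | t0$cyto <= 0 | is.na(t0$mito) | t0$mito <= 0]
  bad <- union(bad, setdiff(unique(traces$cell), t0$cell))
  if (length(bad)) {
    rlang::inform(sprintf(
      "excluding %d cell(s) without a positive frame-0 value", length(bad)))
  }
  out <- traces[!traces$cell %in% bad, , drop = FALSE]
  names(t0) <- c("cell", "cyto0", "mito0", "ratio0")
  out <- dplyr::left_join(out, t0, by = "cell")
  out$cyto_norm <- out$cyto / out$cyto0
  out$mito_norm <- out$mito / out$mito0
  out$ratio_norm <- out$ratio / out$ratio0
  out$cyto0 <- out$mito0 <- out$ratio0 <- NULL
  out <- new_eec_traces(out, fi, nf)
  attr(out, "excluded") <- bad
  out
}
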