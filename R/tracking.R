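#' Link per-frame objects into tracks
#'
#' Frame-to-frame linking by optimal one-to-one assignment (Hungarian
#' algorithm) on centroid distance, gated at `max_displacement`: for every
#' consecutive frame pair the assignment minimizing total displacement among
#' all gated assignments of maximal size is chosen. Unmatched objects start
#' new tracks; unmatched tracks terminate (no gap closing unless
#' `gap_closing = TRUE`, which allows a track that missed one frame to
#' reconnect within `2 * max_displacement`).
#'
#' @param objects Object table from [segment_timelapse()] /
#'   [measure_objects()]: columns `frame` (0-based), `object`, `z`, `y`, `x`
#'   (um).
#' @param max_displacement Maximum allowed centroid displacement between
#'   consecutive frames, um. The default (10) is about two cell radii.
#' @param gap_closing Allow 1-frame gaps?
#' @return A tibble of class `eec_tracks`: `track`, `frame`, `object`, `z`,
#'   `y`, `x`, with attribute `n_frames`.
#' @export
link_objects <- function(objects, max_displacement = 10, gap_closing = FALSE) {
  if (!is.numeric(max_displacement) || max_displacement <= 0) {
    rlang::abort("`max_displacement` must be > 0")
  }
  n_frames <- attr(objects, "n_frames") %||%
    (if (nrow(objects)) max(objects$frame) + 1L else 0L)
  out <- tibble::tibble(track = integer(), frame = integer(),
                        object = integer(), z = numeric(), y = numeric(),
                        x = numeric())
  if (!nrow(objects)) {
    attr(out, "n_frames") <- n_frames
    class(out) <- c("eec_tracks", class(out))
    return(out)
  }

  objects <- dplyr::arrange(objects, .data$frame, .data$object)
  frames <- sort(unique(objects$frame))
  rows <- list()
  next_track <- 0L
  # open tracks: id, last frame, last centroid
  open <- tibble::tibble(track = integer(), last_frame = integer(),
                         z = numeric(), y = numeric(), x = numeric())

  for (f in frames) {
    cur <- objects[objects$frame == f, , drop = FALSE]
    eligible <- open[open$last_frame == f - 1L |
                       (gap_closing & open$last_frame == f - 2L), , drop = FALSE]
    assigned_track <- rep(NA_integer_, nrow(cur))
    if (nrow(eligible) && nrow(cur)) {
      gate <- ifelse(eligible$last_frame == f - 1L,
                     max_displacement, 2 * max_displacement)
      d <- outer(seq_len(nrow(eligible)), seq_len(nrow(cur)),
                 function(i, j) sqrt((eligible$z[i] - cur$z[j])^2 +
                                       (eligible$y[i] - cur$y[j])^2 +
                                       (eligible$x[i] - cur$x[j])^2))
      pairs <- .gated_assignment(d, gate)
      assigned_track[pairs$col] <- eligible$track[pairs$row]
    }
    new_ids <- which(is.na(assigned_track))
    if (length(new_ids)) {
      assigned_track[new_ids] <- next_track + seq_along(new_ids)
      next_track <- next_track + length(new_ids)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      track = assigned_track, frame = cur$frame, object = cur$object,
      z = cur$z, y = cur$y, x = cur$x)
    upd <- tibble::tibble(track = assigned_track, last_frame = f,
                          z = cur$z, y = cur$y, x = cur$x)
    open <- dplyr::bind_rows(open[!open$track %in% upd$track, , drop = FALSE], upd)
  }

  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$track, .data$frame)
  attr(out, "n_frames") <- n_frames
  class(out) <- c("eec_tracks", class(out))
  out
}

# minimum-cost maximal gated assignment via Hungarian on a padded square
# matrix; forbidden links (distance beyond the per-row gate) cost BIG
.gated_assignment <- function(d, gate) {
  BIG <- 1e9
  nr <- nrow(d); nc <- ncol(d)
  n <- max(nr, nc)
  cost <- matrix(0, n, n)
  cost[seq_len(nr), seq_len(nc)] <- ifelse(d <= gate, d, BIG)
  if (nr < n) cost[(nr + 1L):n, seq_len(nc)] <- 0
  if (nc < n) cost[seq_len(nr), (nc + 1L):n] <- 0
  sel <- cpp_hungarian(cost)
  keep <- which(seq_len(n) <= nr & sel <= nc)
  keep <- keep[cost[cbind(keep, sel[keep])] < BIG / 2]
  list(row = keep, col = sel[keep])
}

#' Filter tracks by length and completeness
#'
#' @param tracks An `eec_tracks` tibble from [link_objects()].
#' @param min_length Minimum number of frames a track must span.
#' @param require_complete Keep only tracks covering every frame of the
#'   recording?
#' @param n_frames Recording length; defaults to the attribute set by
#'   [link_objects()].
#' @return The filtered `eec_tracks`.
#' @export
filter_tracks <- function(tracks, min_length = 1L, require_complete = FALSE,
                          n_frames = attr(tracks, "n_frames")) {
  stopifnot(inherits(tracks, "eec_tracks"))
  lens <- table(tracks$track)
  keep <- names(lens)[lens >= min_length]
  if (require_complete) {
    if (is.null(n_frames)) rlang::abort("`n_frames` needed for completeness")
    keep <- intersect(keep, names(lens)[lens == n_frames])
  }
  out <- tracks[tracks$track %in% as.integer(keep), , drop = FALSE]
  attr(out, "n_frames") <- n_frames
  class(out) <- c("eec_tracks", setdiff(class(out), "eec_tracks"))
  out
}

#' Summarize tracks
#'
#' @param tracks An `eec_tracks`.
#' @return One row per track: `track`, `start`, `end`, `length`, `complete`.
#' @export
track_summary <- function(tracks) {
  n_frames <- attr(tracks, "n_frames")
  dplyr::summarise(dplyr::group_by(tracks, .data$track),
                   start = min(.data$frame), end = max(.data$frame),
                   length = dplyr::n(),
                   complete = !is.null(n_frames) && dplyr::n() == n_frames,
                   .groups = "drop")
}
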