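#' Segmentation parameters
#'
#' The per-frame 3D segmentation follows a fixed operator sequence on the
#' cytoplasmic channel: Gaussian smoothing, intensity thresholding, removal of
#' sub-resolution components, watershed separation of touching components, and
#' a volume window filter. Defaults mirror the vendor-analysis settings used
#' for in-vivo EEC imaging: 0.85 um smoothing, removal of objects of
#' equivalent spherical diameter below 1 um, separation distance 0.22 um, and
#' retention of objects between 100 and 1000 um^3.
#'
#' @param smoothing_sigma Gaussian sigma in um (applied per axis in physical
#'   units, so anisotropic voxels are handled correctly).
#' @param min_object_diameter Minimum equivalent spherical diameter, um.
#' @param separation_distance Minimum distance between watershed seed peaks, um.
#' @param volume_min,volume_max Retained object volume window, um^3.
#' @param threshold `"auto"` for Otsu's inter-class-variance threshold on the
#'   smoothed frame, or a single absolute intensity.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smoothing_sigma = 0.85,
                                min_object_diameter = 1,
                                separation_distance = 0.22,
                                volume_min = 100,
                                volume_max = 1000,
                                threshold = "auto") {
  .check_pos(smoothing_sigma, "smoothing_sigma")
  .check_pos(min_object_diameter, "min_object_diameter")
  .check_pos(separation_distance, "separation_distance")
  if (volume_min >= volume_max) rlang::abort("`volume_min` must be < `volume_max`")
  if (!identical(threshold, "auto") &&
      !(is.numeric(threshold) && length(threshold) == 1L)) {
    rlang::abort("`threshold` must be \"auto\" or a single number")
  }
  structure(list(smoothing_sigma = smoothing_sigma,
                 min_object_diameter = min_object_diameter,
                 separation_distance = separation_distance,
                 volume_min = volume_min, volume_max = volume_max,
                 threshold = threshold),
            class = "segmentation_params")
}

#' Otsu's automatic threshold
#'
#' Maximizes the between-class variance on a 256-bin histogram.
#'
#' @param x Numeric vector or array of intensities.
#' @param n_bins Histogram resolution.
#' @return The threshold intensity (a voxel is foreground when strictly above).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (m0[valid] / w0[valid] - (total_m - m0[valid]) / w1[valid])^2 *
    w0[valid] * w1[valid]
  breaks[which.max(between) + 1L]
}

#' Segment one 3D frame of the cytoplasmic channel
#'
#' Applies, in order: (1) Gaussian smoothing with physical sigma
#' `smoothing_sigma`; (2) intensity thresholding (Otsu unless an absolute
#' threshold is given); (3) removal of connected components with equivalent
#' spherical diameter below `min_object_diameter`; (4) marker-based watershed
#' separation of touching components, with seeds at distance-transform peaks
#' at least `separation_distance` apart; (5) removal of components with volume
#' outside `[volume_min, volume_max]`.
#'
#' @param volume Numeric 3D array (z, y, x), one frame of channel 1.
#' @param voxel_size Numeric (z, y, x) voxel size in um.
#' @param params A [segmentation_params()] object.
#' @return Integer label array of the same shape; background is 0, objects are
#'   labelled 1..n. The applied threshold is attached as attribute
#'   `"threshold"`.
#' @export
segment_frame <- function(volume, voxel_size, params = segmentation_params()) {
  if (length(dim(volume)) != 3L) rlang::abort("`volume` must be a 3D array")
  .check_pos(voxel_size, "voxel_size", 3L)
  dims <- dim(volume)

  smoothed <- cpp_gauss3d(as.numeric(volume), dims,
                          params$smoothing_sigma / voxel_size)
  thr <- if (identical(params$threshold, "auto")) otsu_threshold(smoothed)
         else params$threshold
  mask <- smoothed > thr
  if (!any(mask)) {
    lab <- array(0L, dims)
    attr(lab, "threshold") <- thr
    return(lab)
  }

  voxel_vol <- prod(voxel_size)
  lab <- cpp_label3d(as.logical(mask), dims)
  counts <- tabulate(lab[lab > 0L])
  diam <- (6 * counts * voxel_vol / pi)^(1 / 3)
  keep <- which(diam >= params$min_object_diameter)
  mask <- array(lab %in% keep, dims)

  lab <- .separate_objects(mask, voxel_size, params$separation_distance,
                           params$min_object_diameter)

  counts <- tabulate(lab[lab > 0L])
  vols <- counts * voxel_vol
  keep <- which(vols >= params$volume_min & vols <= params$volume_max)
  out <- array(0L, dims)
  if (length(keep)) {
    remap <- integer(length(counts))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    out[pos] <- remap[lab[pos]]
  }
  attr(out, "threshold") <- thr
  out
}

# watershed separation: seeds are plateau-merged local maxima of the
# anisotropic Euclidean distance transform; seeds closer than `sep_dist` um
# are merged (the stronger peak wins). Peaks are located on a distance map
# smoothed at half the minimum object diameter, so voxelization artefacts
# below the resolvable object scale cannot seed a split.
.separate_objects <- function(mask, voxel_size, sep_dist, min_diam = 1) {
  dims <- dim(mask)
  edt <- cpp_edt3d(as.logical(mask), dims, voxel_size)
  edt_s <- cpp_gauss3d(edt, dims, (min_diam / 2) / voxel_size)
  peak <- .local_maxima(edt_s, mask)
  markers <- cpp_label3d(as.logical(peak), dims)
  n_mark <- max(markers)
  if (n_mark > 1L) {
    idx <- which(markers > 0L)
    ind <- arrayInd(idx, dims)
    coords <- sweep(ind - 0.5, 2, voxel_size, `*`)
    height <- vapply(split(edt[idx], markers[idx]), max, numeric(1))
    cz <- vapply(split(coords[, 1], markers[idx]), mean, numeric(1))
    cy <- vapply(split(coords[, 2], markers[idx]), mean, numeric(1))
    cx <- vapply(split(coords[, 3], markers[idx]), mean, numeric(1))
    remap <- seq_len(n_mark)
    ord <- order(height, decreasing = TRUE)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (remap[i] != i) next
      for (b in seq_len(a - 1L)) {
        j <- ord[b]
        if (remap[j] != j) next
        d <- sqrt((cz[i] - cz[j])^2 + (cy[i] - cy[j])^2 + (cx[i] - cx[j])^2)
        if (d < sep_dist) { remap[i] <- j; break }
      }
    }
    if (any(remap != seq_len(n_mark))) {
      pos <- markers > 0L
      markers[pos] <- remap[markers[pos]]
    }
  }
  cpp_watershed3d(edt, markers, as.logical(mask), dims)
}

# 26-neighbourhood local maxima (plateaus included) of `x` within `mask`
.local_maxima <- function(x, mask) {
  dims <- dim(x)
  pad <- -Inf
  nbr_max <- array(-Inf, dims)
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dz == 0 & shifts$dy == 0 & shifts$dx == 0), ]
  for (k in seq_len(nrow(shifts))) {
    sh <- .shift3(x, shifts$dz[k], shifts$dy[k], shifts$dx[k], pad)
    nbr_max <- pmax(nbr_max, sh)
  }
  mask & (x >= nbr_max)
}

# shift a 3D array by (dz, dy, dx), padding with `fill`
.shift3 <- function(x, dz, dy, dx, fill) {
  d <- dim(x)
  out <- array(fill, d)
  src <- list(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  dst <- src
  off <- c(dz, dy, dx)
  for (ax in 1:3) {
    if (off[ax] > 0) {
      dst[[ax]] <- (off[ax] + 1):d[ax]; src[[ax]] <- 1:(d[ax] - off[ax])
    } else if (off[ax] < 0) {
      dst[[ax]] <- 1:(d[ax] + off[ax]); src[[ax]] <- (1 - off[ax]):d[ax]
    }
  }
  out[dst$z, dst$y, dst$x] <- x[src$z, src$y, src$x]
  out
}

#' Measure segmented objects on both channels
#'
#' One row per label: centroid (um), volume (voxel count times voxel volume),
#' and the mean intensity of each channel over the label's voxels.
#'
#' @param labels Integer label array (z, y, x).
#' @param channel1,channel2 Numeric 3D arrays matching `labels`.
#' @param voxel_size Numeric (z, y, x), um.
#' @param frame 0-based frame index recorded in the table.
#' @return A tibble: `frame`, `object`, `volume`, `z`, `y`, `x`, `mean_cyto`,
#'   `mean_mito`, `n_voxels`.
#' @export
measure_objects <- function(labels, channel1, channel2, voxel_size, frame = 0L) {
  stopifnot(identical(dim(labels), dim(channel1)),
            identical(dim(labels), dim(channel2)))
  empty <- tibble::tibble(frame = integer(), object = integer(),
                          volume = numeric(), z = numeric(), y = numeric(),
                          x = numeric(), mean_cyto = numeric(),
                          mean_mito = numeric(), n_voxels = integer())
  idx <- which(labels > 0L)
  if (!length(idx)) return(empty)
  lab <- factor(labels[idx])
  ind <- arrayInd(idx, dim(labels))
  n <- tabulate(lab)
  agg <- function(v) unname(vapply(split(v, lab), sum, numeric(1))) / n
  tibble::tibble(
    frame = as.integer(frame),
    object = as.integer(levels(lab)),
    volume = n * prod(voxel_size),
    z = agg(.vox_center(ind[, 1], voxel_size[1])),
    y = agg(.vox_center(ind[, 2], voxel_size[2])),
    x = agg(.vox_center(ind[, 3], voxel_size[3])),
    mean_cyto = agg(channel1[idx]),
    mean_mito = agg(channel2[idx]),
    n_voxels = n
  )
}

#' Segment and measure every frame of a time-lapse
#'
#' Runs [segment_frame()] on channel 1 of each frame and [measure_objects()]
#' on the result. With `global_threshold = TRUE` the automatic threshold is
#' computed once on frame 0 and reused for all frames, keeping the threshold
#' consistent across one recording.
#'
#' @param timelapse An `eec_timelapse`.
#' @param params A [segmentation_params()].
#' @param global_threshold Reuse the frame-0 automatic threshold for all frames?
#' @param keep_labels Also return the per-frame label arrays?
#' @return A tibble of objects across frames (see [measure_objects()]); when
#'   `keep_labels = TRUE`, the label arrays are attached as attribute
#'   `"labels"` (a list indexed by frame + 1).
#' @export
segment_timelapse <- function(timelapse, params = segmentation_params(),
                              global_threshold = FALSE, keep_labels = FALSE) {
  stopifnot(inherits(timelapse, "eec_timelapse"))
  nf <- dim(timelapse$data)[1]
  vs <- timelapse$voxel_size
  out <- vector("list", nf)
  labs <- if (keep_labels) vector("list", nf) else NULL
  for (t in seq_len(nf)) {
    c1 <- array(timelapse$data[t, 1, , , ], dim(timelapse$data)[3:5])
    c2 <- array(timelapse$data[t, 2, , , ], dim(timelapse$data)[3:5])
    lab <- segment_frame(c1, vs, params)
    if (t == 1L && global_threshold && identical(params$threshold, "auto")) {
      params$threshold <- attr(lab, "threshold")
    }
    out[[t]] <- measure_objects(lab, c1, c2, vs, frame = t - 1L)
    if (keep_labels) labs[[t]] <- lab
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_frames") <- nf
  if (keep_labels) attr(res, "labels") <- labs
  res
}

#' Match segmented objects to ground truth by overlap
#'
#' Greedy best-IoU matching between two label volumes.
#'
#' @param truth_labels,pred_labels Integer label arrays of equal shape.
#' @param iou_threshold Minimum intersection-over-union for a match.
#' @return A tibble with one row per ground-truth object: `truth`, `pred`
#'   (NA when unmatched), `iou`, `matched`.
#' @export
match_objects <- function(truth_labels, pred_labels, iou_threshold = 0.3) {
  t_ids <- sort(unique(truth_labels[truth_labels > 0L]))
  if (!length(t_ids)) {
    return(tibble::tibble(truth = integer(), pred = integer(),
                          iou = numeric(), matched = logical()))
  }
  idx <- which(truth_labels > 0L | pred_labels > 0L)
  tv <- truth_labels[idx]
  pv <- pred_labels[idx]
  t_size <- table(factor(tv[tv > 0L]))
  p_size <- table(factor(pv[pv > 0L]))
  both <- tv > 0L & pv > 0L
  out <- tibble::tibble(truth = as.integer(t_ids), pred = NA_integer_,
                        iou = 0, matched = FALSE)
  if (any(both)) {
    ov <- dplyr::count(tibble::tibble(t = tv[both], p = pv[both]),
                       .data$t, .data$p, name = "inter")
    ov$iou <- ov$inter /
      (as.numeric(t_size[as.character(ov$t)]) +
         as.numeric(p_size[as.character(ov$p)]) - ov$inter)
    best <- dplyr::slice_max(dplyr::group_by(ov, .data$t), .data$iou,
                             n = 1, with_ties = FALSE)
    m <- match(out$truth, best$t)
    hit <- !is.na(m)
    out$pred[hit] <- as.integer(best$p[m[hit]])
    out$iou[hit] <- best$iou[m[hit]]
    out$matched <- out$iou > iou_threshold
  }
  out
}

#' Segmentation recall on a synthetic benchmark
#'
#' Segments every frame of a simulated time-lapse and reports the fraction of
#' visible ground-truth cells matched by a segmented object (IoU above
#' threshold), per frame and averaged.
#'
#' @param sim Output of [generate_timelapse()].
#' @param cfg The generating config.
#' @param params A [segmentation_params()].
#' @param iou_threshold Match criterion.
#' @param global_threshold Passed to [segment_timelapse()] semantics: when
#'   `TRUE` the frame-0 automatic threshold is reused on later frames.
#' @return A list: `per_frame` tibble (`frame`, `n_truth`, `n_matched`,
#'   `recall`) and `recall` (mean over frames, as a percentage).
#' @export
segmentation_recall <- function(sim, cfg, params = segmentation_params(),
                                iou_threshold = 0.3, global_threshold = FALSE) {
  nf <- cfg$n_frames
  vs <- cfg$voxel_size
  thr <- params
  rows <- vector("list", nf)
  for (t in seq_len(nf)) {
    c1 <- array(sim$timelapse$data[t, 1, , , ], cfg$shape)
    lab <- segment_frame(c1, vs, thr)
    if (t == 1L && global_threshold && identical(thr$threshold, "auto")) {
      thr$threshold <- attr(lab, "threshold")
    }
    gt <- ground_truth_labels(sim$truth, cfg, t - 1L)
    mm <- match_objects(gt, lab, iou_threshold)
    rows[[t]] <- tibble::tibble(frame = t - 1L, n_truth = nrow(mm),
                                n_matched = sum(mm$matched),
                                recall = if (nrow(mm)) mean(mm$matched) else NA_real_)
  }
  per_frame <- dplyr::bind_rows(rows)
  list(per_frame = per_frame,
       recall = 100 * mean(per_frame$recall, na.rm = TRUE))
}
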