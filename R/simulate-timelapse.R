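#' Render a ground-truthed two-channel 3D time-lapse
#'
#' Forward-simulates the full acquisition: cells (prolate ellipsoids, long axis
#' along y, basal pole at the -y end) are placed without overlap, their
#' ground-truth traces are rendered into two voxel channels (channel 1
#' cytoplasmic indicator, channel 2 mitochondrial indicator with its spatial
#' mode), rigid scene drift accumulates frame to frame, cells may be lost to
#' "gut motility" (intensity drops to background from a random frame onward),
#' and Gaussian read noise plus Poisson shot noise is applied.
#'
#' @param cfg An [simulation_config()].
#' @return A list with elements
#'   \describe{
#'     \item{timelapse}{an `eec_timelapse`: numeric array `(t, c, z, y, x)`
#'       plus voxel size and frame interval.}
#'     \item{truth}{ground truth: `cells` and `traces` as in
#'       [generate_cell_traces()] plus a `loss_frame` column, and
#'       `trajectories` (`cell`, `frame`, `z`, `y`, `x` in um, `visible`).}
#'   }
#' @examples
#' cfg <- simulation_config(shape = c(16, 48, 48), n_cells = 2, n_frames = 3,
#'                          noise_sd = 0, poisson_scale = 0,
#'                          drift_per_frame = 0, track_loss_rate = 0, seed = 7)
#' sim <- generate_timelapse(cfg)
#' dim(sim$timelapse$data)
#' @export
generate_timelapse <- function(cfg) {
  cfg <- validate_config(cfg)
  set.seed(.derive_seed(cfg$seed, "timelapse"))

  truth <- .generate_cell_traces_impl(cfg)
  centers <- .place_cells(cfg)

  nf <- cfg$n_frames
  n <- cfg$n_cells

  # rigid drift: one cumulative random-direction walk for the whole scene
  drift <- matrix(0, nrow = nf, ncol = 3)
  if (cfg$drift_per_frame > 0 && nf > 1) {
    step <- matrix(rnorm(3 * (nf - 1)), ncol = 3)
    step <- step / sqrt(rowSums(step^2)) * cfg$drift_per_frame
    drift[-1, ] <- apply(step, 2, cumsum)
  }

  # track loss: geometric first-loss frame per cell (frame >= 1)
  loss_frame <- rep(NA_integer_, n)
  if (cfg$track_loss_rate > 0 && n > 0) {
    u <- matrix(runif(n * nf), nrow = n)
    for (i in seq_len(n)) {
      hit <- which(u[i, -1] < cfg$track_loss_rate)
      if (length(hit)) loss_frame[i] <- hit[1]  # 0-based frame of disappearance
    }
  }

  traj <- NULL
  if (n > 0) {
    traj <- tidyr::expand_grid(cell = seq_len(n), frame = seq_len(nf) - 1L)
    traj$z <- centers[traj$cell, 1] + drift[traj$frame + 1L, 1]
    traj$y <- centers[traj$cell, 2] + drift[traj$frame + 1L, 2]
    traj$x <- centers[traj$cell, 3] + drift[traj$frame + 1L, 3]
    traj$visible <- is.na(loss_frame[traj$cell]) | traj$frame < loss_frame[traj$cell]
  } else {
    traj <- tibble::tibble(cell = integer(), frame = integer(), z = numeric(),
                           y = numeric(), x = numeric(), visible = logical())
  }

  data <- array(cfg$background, dim = c(nf, 2L, cfg$shape))
  cyto_m <- if (n > 0) matrix(truth$traces$cyto, nrow = nf) else NULL  # frame x cell
  mito_m <- if (n > 0) matrix(truth$traces$mito, nrow = nf) else NULL
  for (t in seq_len(nf)) {
    for (i in seq_len(n)) {
      if (!is.na(loss_frame[i]) && (t - 1L) >= loss_frame[i]) next
      vox <- .cell_voxels(centers[i, ] + drift[t, ], cfg)
      if (!length(vox$idx)) next
      # linear index into (t, c, z, y, x): t + nf*((c-1) + 2*(vox3d - 1));
      # indicator fluorescence dominates inside a cell, so cell voxels carry
      # the trace value itself and `background` applies only outside
      data[t + nf * (2L * (vox$idx - 1L))] <- cyto_m[t, i]
      data[t + nf * (1L + 2L * (vox$idx - 1L))] <-
        mito_m[t, i] * vox$weight[[truth$cells$mito_mode[i]]]
    }
    if (cfg$poisson_scale > 0) {
      sl <- data[t, , , , , drop = FALSE]
      data[t, , , , ] <- rpois(length(sl), pmax(sl, 0) * cfg$poisson_scale) /
        cfg$poisson_scale
    }
    if (cfg$noise_sd > 0) {
      sl <- data[t, , , , , drop = FALSE]
      data[t, , , , ] <- sl + rnorm(length(sl), 0, cfg$noise_sd)
    }
  }

  truth$cells$loss_frame <- loss_frame
  truth$trajectories <- traj
  list(
    timelapse = new_eec_timelapse(data, cfg$voxel_size, cfg$frame_interval),
    truth = truth
  )
}

#' @rdname generate_timelapse
#' @param data Numeric array `(t, c, z, y, x)`.
#' @param voxel_size Numeric (z, y, x) voxel size in um.
#' @param frame_interval Seconds between frames.
#' @export
new_eec_timelapse <- function(data, voxel_size, frame_interval) {
  stopifnot(length(dim(data)) == 5L)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 frame_interval = frame_interval),
            class = "eec_timelapse")
}

#' @export
print.eec_timelapse <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eec_timelapse> %d frames x %d channels, %dx%dx%d voxels @ %s um, dt=%gs\n",
              d[1], d[2], d[3], d[4], d[5],
              paste(x$voxel_size, collapse = "x"), x$frame_interval))
  invisible(x)
}

#' Rasterize the ground-truth masks of one frame
#'
#' Rebuilds the exact label volume the renderer used for a frame (visible
#' cells only), for photometry checks and segmentation benchmarking.
#'
#' @param truth Ground truth from [generate_timelapse()].
#' @param cfg The generating config.
#' @param frame 0-based frame index.
#' @return Integer label array (z, y, x); labels are ground-truth cell ids.
#' @export
ground_truth_labels <- function(truth, cfg, frame) {
  lab <- array(0L, dim = cfg$shape)
  tr <- truth$trajectories[truth$trajectories$frame == frame &
                             truth$trajectories$visible, , drop = FALSE]
  for (k in seq_len(nrow(tr))) {
    vox <- .cell_voxels(c(tr$z[k], tr$y[k], tr$x[k]), cfg)
    lab[vox$idx] <- tr$cell[k]
  }
  lab
}

# voxel linear indices of an ellipsoid cell at `center` (um, z/y/x), plus the
# per-voxel mitochondrial spatial weights (mean 1 inside the cell)
.cell_voxels <- function(center, cfg) {
  r <- c(cfg$cell_radius, cfg$cell_elongation * cfg$cell_radius, cfg$cell_radius)
  vs <- cfg$voxel_size
  sh <- cfg$shape
  lo <- pmax(1L, ceiling((center - r) / vs))
  hi <- pmin(sh, ceiling((center + r) / vs))
  if (any(lo > hi)) return(list(idx = integer(), weight = NULL))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz <- (.vox_center(zi, vs[1]) - center[1]) / r[1]
  dy <- (.vox_center(yi, vs[2]) - center[2]) / r[2]
  dx <- (.vox_center(xi, vs[3]) - center[3]) / r[3]
  d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  inside <- d2 <= 1
  if (!any(inside)) return(list(idx = integer(), weight = NULL))

  # basal-hotspot weighting: position s along the long (y) axis, 0 = basal pole
  s_y <- (.vox_center(yi, vs[2]) - (center[2] - r[2])) / (2 * r[2])
  s_arr <- array(rep(s_y, each = length(zi)),
                 dim = c(length(zi), length(yi), length(xi)))
  w_hot <- 0.25 + 0.75 * exp(-0.5 * (s_arr / 0.12)^2) / 0.12
  w_hot <- w_hot[inside]
  w_hot <- w_hot / mean(w_hot)

  idx_z <- rep(zi, times = length(yi) * length(xi))
  idx_y <- rep(rep(yi, each = length(zi)), times = length(xi))
  idx_x <- rep(xi, each = length(zi) * length(yi))
  lin <- (idx_z + sh[1] * ((idx_y - 1L) + sh[2] * (idx_x - 1L)))[inside]
  list(idx = lin, weight = list(even = 1, basal_hotspot = w_hot))
}

# rejection-sampled non-overlapping cell centres (pairwise >= 2.5 r apart)
.place_cells <- function(cfg) {
  n <- cfg$n_cells
  if (n == 0L) return(matrix(numeric(), ncol = 3))
  extent <- cfg$shape * cfg$voxel_size
  r <- c(cfg$cell_radius, cfg$cell_elongation * cfg$cell_radius, cfg$cell_radius)
  margin <- r + cfg$drift_per_frame * sqrt(cfg$n_frames) + 0.5
  if (any(extent <= 2 * margin)) {
    rlang::abort("scene too small for the requested cell size and drift margin")
  }
  min_d <- 2.5 * cfg$cell_radius
  centers <- matrix(NA_real_, nrow = n, ncol = 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      rlang::abort(sprintf(
        "could not place %d non-overlapping cells after %d tries", n, max_tries))
    }
    cand <- margin + runif(3) * (extent - 2 * margin)
    if (placed > 0L) {
      d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
      if (any(d < min_d)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}
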