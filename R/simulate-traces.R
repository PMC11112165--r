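#' Generate ground-truth per-cell calcium traces
#'
#' Draws the per-cell trace model described in [simulation_config()]: a
#' cytoplasmic baseline of 1 plus spontaneous transients for active cells and
#' a stimulus transient for responders, and a mitochondrial baseline of 1 that,
#' for responders with mitochondrial coupling on, ramps after a delay to a
#' sustained plateau that never returns to baseline within the recording.
#'
#' Randomness (active/responder assignment, event times, amplitude
#' heterogeneity) is fully determined by `cfg$seed`. A cell's ground-truth
#' `is_active` flag is `TRUE` only if it realized at least one spontaneous
#' event, i.e. the flag describes the generated trace.
#'
#' @param cfg An [simulation_config()] object.
#' @return A list of class `eec_truth` with elements
#'   \describe{
#'     \item{cells}{tibble: `cell`, `is_active`, `is_responder`,
#'       `cyto_amplitude` and `mito_level` (the per-cell realized model
#'       parameters), `mito_mode`.}
#'     \item{traces}{tibble: `cell`, `frame` (0-based), `time` (s), `cyto`,
#'       `mito` (noise-free model values).}
#'   }
#' @examples
#' cfg <- simulation_config(n_cells = 4, active_fraction = 0, seed = 1)
#' truth <- generate_cell_traces(cfg)
#' all(truth$traces$cyto == 1)  # no events -> flat baselines
#' @export
generate_cell_traces <- function(cfg) {
  cfg <- validate_config(cfg)
  set.seed(.derive_seed(cfg$seed, "traces"))
  .generate_cell_traces_impl(cfg)
}

# RNG-consuming core, callable mid-stream by generate_timelapse()
.generate_cell_traces_impl <- function(cfg) {
  n <- cfg$n_cells
  nf <- cfg$n_frames
  dt <- cfg$frame_interval
  tt <- (seq_len(nf) - 1) * dt

  if (n == 0L) {
    return(structure(list(
      cells = tibble::tibble(cell = integer(), is_active = logical(),
                             is_responder = logical(), cyto_amplitude = numeric(),
                             mito_level = numeric(), mito_mode = character()),
      traces = tibble::tibble(cell = integer(), frame = integer(),
                              time = numeric(), cyto = numeric(), mito = numeric())
    ), class = "eec_truth"))
  }

  assigned_active <- runif(n) < cfg$active_fraction
  is_responder <- if (is.null(cfg$stimulus_frame)) rep(FALSE, n)
                  else runif(n) < cfg$responder_fraction

  # lognormal heterogeneity factor, mean 1
  cv <- cfg$amplitude_cv
  het <- if (cv > 0) exp(rnorm(n, -cv^2 / 2, cv)) else rep(1, n)
  mito_jit <- if (cv > 0) exp(rnorm(n, -(cv / 2)^2 / 2, cv / 2)) else rep(1, n)
  cyto_amp <- ifelse(is_responder, cfg$cyto_peak_amplitude * het, 0)
  mito_lvl <- ifelse(is_responder & cfg$mito_coupling,
                     cfg$mito_sustained_level * het * mito_jit, 0)

  mito_mode <- switch(cfg$mito_mode,
    even = rep("even", n),
    basal_hotspot = rep("basal_hotspot", n),
    mixed = ifelse(runif(n) < cfg$hotspot_fraction, "basal_hotspot", "even")
  )

  traces <- vector("list", n)
  realized_active <- logical(n)
  for (i in seq_len(n)) {
    cyto <- rep(1, nf)
    if (assigned_active[i] && cfg$spontaneous_event_rate > 0 && nf > 1) {
      ev <- rpois(nf - 1L, cfg$spontaneous_event_rate)  # events at frames 0..nf-2
      realized_active[i] <- sum(ev) > 0
      for (k in which(ev > 0)) {
        te <- tt[k]
        post <- tt >= te
        cyto[post] <- cyto[post] +
          ev[k] * cfg$spontaneous_amplitude *
          exp(-(tt[post] - te) / cfg$spontaneous_decay_tau)
      }
    }
    mito <- rep(1, nf)
    if (is_responder[i]) {
      ts <- cfg$stimulus_frame * dt
      post <- tt >= ts
      cyto[post] <- cyto[post] + cyto_amp[i] * exp(-(tt[post] - ts) / cfg$cyto_decay_tau)
      if (cfg$mito_coupling) {
        ramp <- pmin(pmax((tt - ts - cfg$mito_delay) / cfg$mito_rise_time, 0), 1)
        mito <- mito + mito_lvl[i] * ramp
      }
    }
    traces[[i]] <- tibble::tibble(cell = i, frame = seq_len(nf) - 1L,
                                  time = tt, cyto = cyto, mito = mito)
  }

  structure(list(
    cells = tibble::tibble(
      cell = seq_len(n),
      is_active = assigned_active & realized_active,
      is_responder = is_responder,
      cyto_amplitude = cyto_amp,
      mito_level = mito_lvl,
      mito_mode = mito_mode
    ),
    traces = dplyr::bind_rows(traces)
  ), class = "eec_truth")
}

#' Add photometric measurement noise to ground-truth traces
#'
#' Emulates what trace extraction from the rendered voxel data measures: each
#' per-frame cell mean carries Gaussian read noise plus Poisson shot noise,
#' attenuated by averaging over the cell's voxels. Useful for fast
#' parameter-recovery studies that do not need the full voxel render.
#'
#' @param truth An `eec_truth` from [generate_cell_traces()].
#' @param cfg The generating [simulation_config()].
#' @param seed Optional seed (defaults to a stream derived from `cfg$seed`).
#' @return Traces in the [extract_traces()] layout (`cell`, `frame`, `cyto`,
#'   `mito`, `ratio`), class `eec_traces`.
#' @export
observe_traces <- function(truth, cfg, seed = NULL) {
  stopifnot(inherits(truth, "eec_truth"))
  set.seed(seed %||% .derive_seed(cfg$seed, "observe"))
  voxel_vol <- prod(cfg$voxel_size)
  n_vox <- max(1, round(.cell_volume(cfg) / voxel_vol))
  tr <- truth$traces
  noisy <- function(v) {
    var_shot <- if (cfg$poisson_scale > 0) v / cfg$poisson_scale else 0
    v + rnorm(length(v), 0, sqrt((cfg$noise_sd^2 + var_shot) / n_vox))
  }
  out <- tibble::tibble(cell = tr$cell, frame = tr$frame,
                        cyto = noisy(tr$cyto), mito = noisy(tr$mito))
  out$ratio <- out$mito / out$cyto
  new_eec_traces(out, frame_interval = cfg$frame_interval,
                 n_frames = cfg$n_frames)
}

# ellipsoid cell volume in um^3 (semi-axes r, 1.5r, r)
.cell_volume <- function(cfg) {
  4 / 3 * pi * cfg$cell_radius^2 * (cfg$cell_elongation * cfg$cell_radius)
}
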