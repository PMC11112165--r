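#' Configuration for the synthetic EEC time-lapse generator
#'
#' Bundles every knob of the forward simulation: scene geometry, the per-cell
#' calcium trace model, the mitochondrial spatial model, the noise model and
#' acquisition artefacts. All lengths are in micrometres, all times in seconds,
#' and frame indices are 0-based. A fixed `seed` makes the whole simulation
#' (traces, placement, drift, noise) reproducible voxel for voxel.
#'
#' The trace model: every cell has a cytoplasmic baseline of 1 (arbitrary
#' units). Active cells add spontaneous low-amplitude transients (instant rise
#' of `spontaneous_amplitude`, exponential decay with `spontaneous_decay_tau`)
#' at Poisson-distributed frames. If a stimulus is given at `stimulus_frame`,
#' responder cells add a stimulus transient: an instant rise of
#' `cyto_peak_amplitude` that decays back to baseline with time constant
#' `cyto_decay_tau`. When `mito_coupling` is on, responder mitochondrial traces
#' ramp up, after a lag of `mito_delay` seconds, linearly over
#' `mito_rise_time` seconds to a plateau of `1 + mito_sustained_level` that is
#' held to the end of the recording; with coupling off (the germ-free-like
#' phenotype) mitochondrial traces stay at baseline.
#'
#' Per-cell heterogeneity: each responder draws a lognormal factor with
#' coefficient of variation `amplitude_cv` (mean 1) that scales both its
#' cytoplasmic peak and its mitochondrial plateau, so the two amplitudes are
#' positively coupled across cells when `mito_coupling` is on. Set
#' `amplitude_cv = 0` for the exact closed-form traces.
#'
#' @param shape Integer vector (z, y, x): scene size in voxels.
#' @param voxel_size Numeric vector (z, y, x): voxel edge lengths in um.
#' @param n_frames Number of time frames.
#' @param frame_interval Seconds between frames (default 10).
#' @param n_cells Number of cells placed in the scene.
#' @param cell_radius Equatorial radius of the prolate-ellipsoid cell body, um.
#'   The long axis (1.5x) runs along y with the basal pole at the -y end.
#' @param active_fraction Probability that a cell is spontaneously active.
#' @param spontaneous_event_rate Expected spontaneous events per frame for
#'   active cells.
#' @param spontaneous_amplitude Relative amplitude of a spontaneous transient.
#' @param spontaneous_decay_tau Decay time constant of spontaneous transients, s.
#' @param stimulus_frame 0-based frame of the stimulus, or `NULL` for a resting
#'   recording.
#' @param responder_fraction Probability that a cell responds to the stimulus.
#' @param cyto_peak_amplitude Relative cytoplasmic peak of a responder.
#' @param cyto_decay_tau Decay time constant of the stimulus transient, s.
#' @param mito_delay Lag between the stimulus and the mitochondrial rise, s.
#' @param mito_rise_time Duration of the linear mitochondrial rise, s.
#' @param mito_sustained_level Relative height of the sustained mitochondrial
#'   plateau.
#' @param mito_coupling Logical; couple mitochondrial traces to the stimulus?
#' @param amplitude_cv Lognormal coefficient of variation of per-cell response
#'   amplitudes (0 = identical cells).
#' @param mito_mode Spatial distribution of the mitochondrial channel inside a
#'   cell: `"even"`, `"basal_hotspot"`, or `"mixed"` (per-cell Bernoulli draw
#'   with probability `hotspot_fraction` of being a hotspot cell).
#' @param hotspot_fraction Probability a cell is a hotspot cell under
#'   `mito_mode = "mixed"`.
#' @param background Background intensity level, a.u.
#' @param noise_sd Gaussian read-noise standard deviation, a.u. (0 disables).
#' @param poisson_scale Photons per intensity unit for shot noise (0 disables).
#' @param drift_per_frame Magnitude of the rigid scene drift per frame, um.
#' @param track_loss_rate Per-frame probability that a cell is lost (its
#'   intensity drops to background for the rest of the recording), emulating
#'   gut-motility track loss.
#' @param seed Integer seed fixing all randomness.
#'
#' @return A validated `eec_sim_config` list.
#' @seealso [generate_cell_traces()], [generate_timelapse()], [preset_cv()],
#'   [benchmark_config()]
#' @export
simulation_config <- function(shape = c(32L, 96L, 192L),
                              voxel_size = c(1.0, 0.5, 0.5),
                              n_frames = 40L,
                              frame_interval = 10,
                              n_cells = 20L,
                              cell_radius = 3.5,
                              active_fraction = 0.21,
                              spontaneous_event_rate = 0.05,
                              spontaneous_amplitude = 0.4,
                              spontaneous_decay_tau = 20,
                              stimulus_frame = NULL,
                              responder_fraction = 0,
                              cyto_peak_amplitude = 0.8,
                              cyto_decay_tau = 30,
                              mito_delay = 10,
                              mito_rise_time = 30,
                              mito_sustained_level = 0.4,
                              mito_coupling = TRUE,
                              amplitude_cv = 0.3,
                              mito_mode = c("basal_hotspot", "even", "mixed"),
                              hotspot_fraction = 0.7,
                              background = 0.1,
                              noise_sd = 0.05,
                              poisson_scale = 200,
                              drift_per_frame = 0.5,
                              track_loss_rate = 0.01,
                              seed = 1L) {
  mito_mode <- match.arg(mito_mode)
  cfg <- list(
    shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    n_cells = as.integer(n_cells), cell_radius = cell_radius,
    cell_elongation = 1.5,
    active_fraction = active_fraction,
    spontaneous_event_rate = spontaneous_event_rate,
    spontaneous_amplitude = spontaneous_amplitude,
    spontaneous_decay_tau = spontaneous_decay_tau,
    stimulus_frame = if (is.null(stimulus_frame)) NULL else as.integer(stimulus_frame),
    responder_fraction = responder_fraction,
    cyto_peak_amplitude = cyto_peak_amplitude,
    cyto_decay_tau = cyto_decay_tau,
    mito_delay = mito_delay, mito_rise_time = mito_rise_time,
    mito_sustained_level = mito_sustained_level,
    mito_coupling = isTRUE(mito_coupling),
    amplitude_cv = amplitude_cv,
    mito_mode = mito_mode, hotspot_fraction = hotspot_fraction,
    background = background, noise_sd = noise_sd,
    poisson_scale = poisson_scale,
    drift_per_frame = drift_per_frame,
    track_loss_rate = track_loss_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "eec_sim_config"
  validate_config(cfg)
}

#' @rdname simulation_config
#' @param cfg An `eec_sim_config` object.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "eec_sim_config"))
  if (length(cfg$shape) != 3L || any(cfg$shape < 1L)) {
    rlang::abort("`shape` must be three positive voxel counts (z, y, x)")
  }
  .check_pos(cfg$voxel_size, "voxel_size", 3L)
  .check_pos(cfg$frame_interval, "frame_interval")
  .check_pos(cfg$cell_radius, "cell_radius")
  if (cfg$n_frames < 1L) rlang::abort("`n_frames` must be >= 1")
  if (cfg$n_cells < 0L) rlang::abort("`n_cells` must be >= 0")
  for (p in c("active_fraction", "responder_fraction", "track_loss_rate",
              "hotspot_fraction")) {
    .check_prob(cfg[[p]], p)
  }
  if (!is.null(cfg$stimulus_frame)) {
    if (cfg$stimulus_frame < 0L || cfg$stimulus_frame >= cfg$n_frames) {
      rlang::abort("`stimulus_frame` must lie in [0, n_frames)")
    }
  } else if (cfg$responder_fraction > 0) {
    rlang::abort(paste(
      "stimulus-response parameters set without `stimulus_frame`:",
      "`responder_fraction` > 0 requires a stimulus"
    ))
  }
  if (cfg$noise_sd < 0 || cfg$poisson_scale < 0 || cfg$drift_per_frame < 0 ||
      cfg$amplitude_cv < 0) {
    rlang::abort("noise, drift and amplitude_cv parameters must be >= 0")
  }
  cfg
}

#' Study-condition presets
#'
#' `preset_cv()` parameterizes the conventionalized (microbiota-colonized)
#' phenotype for a stimulus recording: roughly half of the cells respond to
#' the nutrient pulse, and mitochondrial coupling is on so responders show the
#' delayed, sustained mitochondrial elevation. `preset_gf()` parameterizes the
#' germ-free phenotype: a reduced responder fraction and no mitochondrial
#' coupling, so nutrient-evoked mitochondrial activation is absent.
#' `benchmark_config()` is the fixed segmentation benchmark scene: 60 cells in
#' a larger volume, default noise, 0.5 um/frame rigid drift.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return An `eec_sim_config`.
#' @export
preset_cv <- function(seed = 1L, ...) {
  args <- list(stimulus_frame = 10L, responder_fraction = 0.5,
               mito_coupling = TRUE, active_fraction = 0.21, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' @rdname preset_cv
#' @export
preset_gf <- function(seed = 1L, ...) {
  args <- list(stimulus_frame = 10L, responder_fraction = 0.2,
               mito_coupling = FALSE, active_fraction = 0.025, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' @rdname preset_cv
#' @export
benchmark_config <- function(seed = 1L, ...) {
  args <- list(shape = c(32L, 128L, 256L), n_cells = 60L, n_frames = 12L,
               drift_per_frame = 0.5, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' @export
print.eec_sim_config <- function(x, ...) {
  cat("<eec_sim_config>\n")
  cat(sprintf("  scene: %s voxels @ %s um, %d frames x %gs\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_size, collapse = "x"),
              x$n_frames, x$frame_interval))
  cat(sprintf("  cells: %d (radius %g um), active %.0f%%, responders %.0f%%%s\n",
              x$n_cells, x$cell_radius, 100 * x$active_fraction,
              100 * x$responder_fraction,
              if (is.null(x$stimulus_frame)) " (no stimulus)"
              else sprintf(" (stimulus @ frame %d)", x$stimulus_frame)))
  cat(sprintf("  mito: coupling %s, mode %s; noise sd %g / %g photons; seed %d\n",
              if (x$mito_coupling) "on" else "off", x$mito_mode,
              x$noise_sd, x$poisson_scale, x$seed))
  invisible(x)
}
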