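# small noise-free scene reused across photometry checks
noise_free_cfg <- simulation_config(
  shape = c(16L, 48L, 64L), n_cells = 2, n_frames = 6,
  active_fraction = 0, stimulus_frame = 2L, responder_fraction = 1,
  amplitude_cv = 0, noise_sd = 0, poisson_scale = 0,
  drift_per_frame = 0, track_loss_rate = 0, seed = 11)

test_that("rendered channel sums reproduce the analytic traces", {
  sim <- generate_timelapse(noise_free_cfg)
  cfg <- noise_free_cfg
  for (cell in 1:2) {
    sums <- vapply(seq_len(cfg$n_frames), function(t) {
      gt <- ground_truth_labels(sim$truth, cfg, t - 1L)
      frame <- array(sim$timelapse$data[t, 1, , , ], cfg$shape)
      sum(frame[gt == cell])
    }, numeric(1))
    truth_trace <- sim$truth$traces$cyto[sim$truth$traces$cell == cell]
    expect_gt(stats::cor(sums, truth_trace), 0.999)
  }
})

test_that("mitochondrial channel mean tracks the mito trace", {
  sim <- generate_timelapse(noise_free_cfg)
  cfg <- noise_free_cfg
  gt0 <- ground_truth_labels(sim$truth, cfg, 0L)
  n_vox <- sum(gt0 == 1)
  means <- vapply(seq_len(cfg$n_frames), function(t) {
    frame <- array(sim$timelapse$data[t, 2, , , ], cfg$shape)
    mean(frame[ground_truth_labels(sim$truth, cfg, t - 1L) == 1])
  }, numeric(1))
  truth_trace <- sim$truth$traces$mito[sim$truth$traces$cell == 1]
  # spatial weights have mean 1 inside the cell, so the cell mean equals the
  # trace regardless of the distribution mode
  expect_equal(means, truth_trace, tolerance = 1e-10)
  expect_gt(n_vox, 0)
})

test_that("an empty scene renders background only", {
  cfg <- simulation_config(shape = c(8L, 24L, 24L), n_cells = 0, n_frames = 2,
                           noise_sd = 0, poisson_scale = 0, seed = 1)
  sim <- generate_timelapse(cfg)
  expect_true(all(sim$timelapse$data == cfg$background))
  expect_equal(nrow(sim$truth$cells), 0L)
  expect_equal(nrow(sim$truth$trajectories), 0L)
})

test_that("the same seed reproduces voxel-identical stacks", {
  cfg <- simulation_config(shape = c(12L, 40L, 40L), n_cells = 2, n_frames = 3,
                           drift_per_frame = 0.3, seed = 99)
  a <- generate_timelapse(cfg)
  b <- generate_timelapse(cfg)
  expect_identical(a$timelapse$data, b$timelapse$data)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("cells are placed without overlap and inside bounds", {
  cfg <- simulation_config(shape = c(24L, 96L, 96L), n_cells = 12,
                           drift_per_frame = 0, n_frames = 1, seed = 4)
  sim <- generate_timelapse(cfg)
  pos <- sim$truth$trajectories[sim$truth$trajectories$frame == 0, ]
  d <- as.matrix(stats::dist(pos[, c("z", "y", "x")]))
  diag(d) <- Inf
  expect_gte(min(d), 2.5 * cfg$cell_radius)
  extent <- cfg$shape * cfg$voxel_size
  expect_true(all(pos$z > 0 & pos$z < extent[1]))
  expect_true(all(pos$y > 0 & pos$y < extent[2]))
  expect_true(all(pos$x > 0 & pos$x < extent[3]))
})

test_that("impossible placement raises a placement error", {
  expect_error(
    generate_timelapse(simulation_config(shape = c(16L, 40L, 40L),
                                         n_cells = 500, n_frames = 1,
                                         drift_per_frame = 0, seed = 1)),
    "place|small")
})

test_that("track loss hides cells from their loss frame onward", {
  cfg <- simulation_config(shape = c(16L, 48L, 64L), n_cells = 4, n_frames = 20,
                           track_loss_rate = 0.2, drift_per_frame = 0,
                           noise_sd = 0, poisson_scale = 0,
                           active_fraction = 0, seed = 21)
  sim <- generate_timelapse(cfg)
  lost <- which(!is.na(sim$truth$cells$loss_frame))
  expect_gt(length(lost), 0)
  i <- lost[1]
  lf <- sim$truth$cells$loss_frame[i]
  gt_before <- ground_truth_labels(sim$truth, cfg, lf - 1L)
  gt_after <- ground_truth_labels(sim$truth, cfg, lf)
  expect_gt(sum(gt_before == i), 0)
  expect_equal(sum(gt_after == i), 0)
  # the rendered frame really is background there
  frame <- array(sim$timelapse$data[lf + 1L, 1, , , ], cfg$shape)
  expect_true(all(frame[gt_before == i] == cfg$background))
})

test_that("basal-hotspot rendering puts at least half the mass basally", {
  cfg <- simulation_config(shape = c(16L, 48L, 64L), n_cells = 3, n_frames = 1,
                           mito_mode = "basal_hotspot", noise_sd = 0,
                           poisson_scale = 0, drift_per_frame = 0,
                           active_fraction = 0, seed = 8)
  sim <- generate_timelapse(cfg)
  gt <- ground_truth_labels(sim$truth, cfg, 0L)
  frame <- array(sim$timelapse$data[1, 2, , , ], cfg$shape)
  for (cell in 1:3) {
    idx <- which(gt == cell)
    ind <- arrayInd(idx, cfg$shape)
    y <- (ind[, 2] - 0.5) * cfg$voxel_size[2]
    signal <- frame[idx]
    ylen <- diff(range(y))
    basal <- y <= min(y) + 0.25 * ylen
    expect_gte(sum(signal[basal]) / sum(signal), 0.5)
  }
})

test_that("time-lapse TIFF round trip preserves data and metadata", {
  cfg <- simulation_config(shape = c(16L, 48L, 64L), n_cells = 1, n_frames = 2,
                           drift_per_frame = 0, seed = 6)
  sim <- generate_timelapse(cfg)
  path <- withr::local_tempfile(fileext = ".tif")
  write_timelapse(sim$timelapse, path)
  back <- read_timelapse(path)
  expect_equal(back$data, sim$timelapse$data, tolerance = 1e-6)
  expect_equal(back$voxel_size, cfg$voxel_size)
  expect_equal(back$frame_interval, cfg$frame_interval)
})
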