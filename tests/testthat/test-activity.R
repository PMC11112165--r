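# build an eec_traces object directly from per-cell cyto/mito vectors
make_traces <- function(cyto, mito = NULL, frame_interval = 10) {
  rows <- lapply(seq_along(cyto), function(i) {
    n <- length(cyto[[i]])
    m <- if (is.null(mito)) rep(1, n) else mito[[i]]
    tibble::tibble(cell = i, frame = seq_len(n) - 1L, cyto = cyto[[i]],
                   mito = m, ratio = m / cyto[[i]])
  })
  new_eec_traces(dplyr::bind_rows(rows), frame_interval)
}

test_that("normalize_to_t0 divides by the first value and is idempotent", {
  expect_equal(normalize_to_t0(c(2, 4, 6)), c(1, 2, 3))
  expect_equal(normalize_to_t0(rep(7, 5)), rep(1, 5))
  x <- c(1.5, 2.25, 0.75)
  expect_equal(normalize_to_t0(normalize_to_t0(x)), normalize_to_t0(x))
  expect_equal(normalize_to_t0(x)[1], 1)
  expect_error(normalize_to_t0(c(0, 1)), "positive")
})

test_that("cells without a positive t0 are excluded with a message", {
  tr <- make_traces(list(c(2, 3), c(NA, 3)))
  expect_message(norm <- normalize_traces(tr), "excluding 1")
  expect_equal(unique(norm$cell), 1L)
  expect_equal(attr(norm, "excluded"), 2L)
})

test_that("spontaneous activity requires persistent suprathreshold excursion", {
  flat <- rep(1, 20)
  spike1 <- replace(rep(1, 20), 10, 1.5)          # one frame only
  burst <- replace(rep(1, 20), 10:12, c(1.5, 1.3, 1.25))
  act <- classify_spontaneous(make_traces(list(flat, spike1, burst)))
  expect_equal(act$active, c(FALSE, FALSE, TRUE))
  expect_equal(attr(act, "percent_active"), 100 / 3)
  expect_equal(glance(act)$n_active, 1L)

  none <- classify_spontaneous(make_traces(list(flat, flat)))
  expect_equal(attr(none, "percent_active"), 0)
})

test_that("responder detection uses the post-stimulus window only", {
  pre_only <- replace(rep(1, 20), 3, 1.9)   # spike before the stimulus
  resp <- replace(rep(1, 20), 12:14, c(1.8, 1.5, 1.3))
  flat <- rep(1, 20)
  r <- detect_stimulus_responders(make_traces(list(pre_only, resp, flat)),
                                  stimulus_frame = 10L)
  expect_equal(r$responder, c(FALSE, TRUE, FALSE))
  expect_equal(attr(r, "percent_responders"), 100 / 3)
  expect_error(detect_stimulus_responders(make_traces(list(flat)), 25L),
               "outside")
})

test_that("response metrics recover the generator's closed-form quantities", {
  cfg <- simulation_config(n_cells = 12, active_fraction = 0,
                           stimulus_frame = 10L, responder_fraction = 1,
                           amplitude_cv = 0, noise_sd = 0, poisson_scale = 0,
                           mito_sustained_level = 0.4, seed = 23)
  truth <- generate_cell_traces(cfg)
  tr <- truth$traces
  traces <- new_eec_traces(
    tibble::tibble(cell = tr$cell, frame = tr$frame, cyto = tr$cyto,
                   mito = tr$mito, ratio = tr$mito / tr$cyto),
    cfg$frame_interval)
  rec <- response_metrics(traces, 10L)
  expect_true(all(rec$responder))
  expect_equal(rec$cyto_amplitude, rep(cfg$cyto_peak_amplitude, 12))
  # plateau reached well before the final quartile: exact recovery
  expect_true(all(abs(rec$sustained_index - 0.4) < 0.02))
  # cyto back at baseline while mito stays up -> ratio change positive
  expect_true(all(rec$ratio_change > 0))
})

test_that("coupling off gives flat mitochondrial response metrics", {
  cfg <- simulation_config(n_cells = 8, active_fraction = 0,
                           stimulus_frame = 10L, responder_fraction = 1,
                           mito_coupling = FALSE, amplitude_cv = 0,
                           noise_sd = 0, poisson_scale = 0, seed = 29)
  truth <- generate_cell_traces(cfg)
  tr <- truth$traces
  traces <- new_eec_traces(
    tibble::tibble(cell = tr$cell, frame = tr$frame, cyto = tr$cyto,
                   mito = tr$mito, ratio = tr$mito / tr$cyto),
    cfg$frame_interval)
  rec <- response_metrics(traces, 10L)
  expect_true(all(abs(rec$mito_amplitude) < 1e-12))
  expect_true(all(abs(rec$sustained_index) < 1e-12))
})

test_that("ATP responder rule is a strict 15% increase", {
  d <- data.frame(cell = 1:3, ratio_t0 = c(1, 1, 1),
                  ratio_end = c(1.20, 1.10, 1.15))
  r <- classify_atp_responders(d)
  expect_equal(r$responder, c(TRUE, FALSE, FALSE))
  d2 <- data.frame(cell = 1:2, ratio_t0 = c(0, 1), ratio_end = c(1, 1.3))
  expect_message(r2 <- classify_atp_responders(d2), "excluding 1")
  expect_equal(r2$cell, 2L)
})

test_that("amplitude correlation handles collinear and short inputs", {
  rec <- tibble::tibble(cell = 1:4, cyto_amplitude = c(0, 1, 2, 3),
                        mito_amplitude = c(0, 2, 4, 6),
                        responder = TRUE)
  out <- amplitude_correlation(rec)
  expect_equal(out$r, 1)
  expect_warning(short <- amplitude_correlation(rec[1:2, ]), "fewer than 3")
  expect_true(is.na(short$r))
})

test_that("hierarchical clustering matches brute-force average linkage", {
  set.seed(41)
  shapes <- rbind(sin(seq(0, 2 * pi, length.out = 15)),
                  cos(seq(0, 2 * pi, length.out = 15)),
                  seq(0, 1, length.out = 15))
  m <- shapes[c(1, 1, 2, 2, 3, 3), ] + matrix(rnorm(90, 0, 0.05), 6)
  traces <- make_traces(lapply(seq_len(6), function(i) 2 + m[i, ]))
  norm <- normalize_traces(traces)

  cl <- cluster_traces(norm, k = 3)
  wide <- matrix(norm$cyto_norm, nrow = 6, byrow = TRUE)
  dmat <- 1 - cor(t(wide))
  oracle <- brute_average_linkage(dmat)
  tree <- attr(cl, "tree")
  expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-10)
  for (k in c(2, 3)) {
    got <- canon_partition(cutree(tree, k))
    want <- canon_partition(partition_vector(
      oracle$partitions[[6 - k]], 6))
    expect_equal(got, want)
  }
  # two repeated shapes, k = 2 separates the shape groups
  cl2 <- cluster_traces(normalize_traces(make_traces(list(
    2 + shapes[1, ], 2 + shapes[1, ], 2 + shapes[3, ], 2 + shapes[3, ]))), k = 2)
  expect_equal(canon_partition(cl2$cluster), c(1, 1, 2, 2))
  expect_error(cluster_traces(norm, k = 10), "fewer")
})

test_that("group comparisons reproduce textbook t-test behaviour", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(paired0 <- compare_groups(c(1, 2, 3), c(1, 2, 3),
                                           paired = TRUE), "degenerate")
  expect_equal(paired0$statistic, 0)
  expect_equal(paired0$p_value, 1)

  set.seed(5)
  a <- c(0, 0, 0, 0) + rnorm(4, 0, 1e-3)
  b <- c(1, 1, 1, 1) + rnorm(4, 0, 1e-3)
  expect_lt(compare_groups(a, b)$p_value, 1e-3)

  # pooled-variance check against the closed form
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(compare_groups(x, y)$statistic, t_manual)
})

test_that("anova with Tukey reports the expected contrasts", {
  set.seed(9)
  vals <- c(rnorm(10, 0), rnorm(10, 0.1), rnorm(10, 3))
  grp <- rep(c("a", "b", "c"), each = 10)
  out <- compare_groups_anova(vals, grp)
  expect_lt(out$anova$p_value, 1e-6)
  expect_equal(nrow(out$tukey), 3L)
  expect_lt(out$tukey$p_adj[out$tukey$contrast == "c-a"], 0.001)
  expect_gt(out$tukey$p_adj[out$tukey$contrast == "b-a"], 0.05)
})

test_that("scalar summaries are invariant to cell order", {
  cfg <- preset_cv(n_cells = 30, seed = 51)
  truth <- generate_cell_traces(cfg)
  obs <- observe_traces(truth, cfg)
  norm <- normalize_traces(obs)
  shuffled <- norm[order(rev(seq_len(nrow(norm)))), ]
  shuffled <- new_eec_traces(shuffled, attr(norm, "frame_interval"),
                             attr(norm, "n_frames"))
  expect_equal(attr(classify_spontaneous(norm), "percent_active"),
               attr(classify_spontaneous(shuffled), "percent_active"))
  r1 <- response_metrics(norm, cfg$stimulus_frame)
  r2 <- response_metrics(shuffled, cfg$stimulus_frame)
  expect_equal(suppressWarnings(amplitude_correlation(r1))$r,
               suppressWarnings(amplitude_correlation(r2))$r)
})

test_that("absent frames stay absent in extracted traces", {
  obj <- tibble::tibble(frame = c(0L, 1L, 2L, 3L, 4L, 5L, 8L, 9L),
                        object = 1L,
                        z = 1, y = 1, x = 1,
                        mean_cyto = 10, mean_mito = 20)
  attr(obj, "n_frames") <- 10L
  trk <- tibble::tibble(track = 1L, frame = obj$frame, object = 1L,
                        z = 1, y = 1, x = 1)
  attr(trk, "n_frames") <- 10L
  class(trk) <- c("eec_tracks", class(trk))
  tr <- extract_traces(trk, obj)
  expect_equal(nrow(tr), 10L)
  expect_true(all(is.na(tr$cyto[tr$frame %in% 6:7])))
  expect_true(all(!is.na(tr$cyto[!tr$frame %in% 6:7])))
  expect_equal(unique(tr$ratio[!is.na(tr$ratio)]), 2)
})
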