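# object table from a matrix of centroids per frame
toy_objects <- function(...) {
  frames <- list(...)
  rows <- lapply(seq_along(frames), function(f) {
    m <- frames[[f]]
    tibble::tibble(frame = f - 1L, object = seq_len(nrow(m)),
                   z = m[, 1], y = m[, 2], x = m[, 3],
                   mean_cyto = 1, mean_mito = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_frames") <- length(frames)
  out
}

test_that("a single object per frame forms one full-length track", {
  obj <- toy_objects(matrix(c(5, 5, 5), 1), matrix(c(5, 6, 5), 1),
                     matrix(c(5, 7, 5), 1))
  trk <- link_objects(obj, max_displacement = 5)
  expect_equal(length(unique(trk$track)), 1L)
  expect_equal(nrow(trk), 3L)
  expect_true(track_summary(trk)$complete)
})

test_that("linking matches exhaustive gated assignment on small instances", {
  set.seed(31)
  for (rep in 1:8) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    f1 <- cbind(runif(n1, 0, 20), runif(n1, 0, 20), runif(n1, 0, 20))
    f2 <- cbind(runif(n2, 0, 20), runif(n2, 0, 20), runif(n2, 0, 20))
    gate <- 12
    trk <- link_objects(toy_objects(f1, f2), max_displacement = gate)

    d <- outer(seq_len(n1), seq_len(n2), function(i, j) {
      sqrt(rowSums((f1[i, , drop = FALSE] - f2[j, , drop = FALSE])^2))
    })
    oracle <- brute_assignment(d, gate)

    linked <- dplyr::inner_join(trk[trk$frame == 0L, c("track", "object")],
                                trk[trk$frame == 1L, c("track", "object")],
                                by = "track")
    expect_equal(nrow(linked), length(oracle$row))
    if (nrow(linked)) {
      got <- sum(d[cbind(linked$object.x, linked$object.y)])
      expect_equal(got, sum(d[cbind(oracle$row, oracle$col)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("objects jumping beyond the gate terminate rather than swap", {
  # two objects cross past each other so that every candidate link — keeping
  # identity or swapping it — exceeds the gate: both tracks must end and two
  # new ones start, matching exhaustive enumeration on the 2-object toy
  f1 <- rbind(c(5, 5, 0), c(5, 5, 26))
  f2 <- rbind(c(5, 5, 14), c(5, 5, 12))
  d <- outer(1:2, 1:2, function(i, j) abs(f1[i, 3] - f2[j, 3]))
  expect_true(all(d > 10))
  expect_equal(length(brute_assignment(d, 10)$row), 0L)
  trk <- link_objects(toy_objects(f1, f2), max_displacement = 10)
  expect_equal(length(unique(trk$track)), 4L)
  expect_true(all(table(trk$track) == 1L))
})

test_that("static synthetic scene is tracked without identity switches", {
  cfg <- simulation_config(shape = c(24L, 96L, 128L), n_cells = 20,
                           n_frames = 8, drift_per_frame = 0,
                           track_loss_rate = 0, active_fraction = 0,
                           seed = 13)
  sim <- generate_timelapse(cfg)
  obj <- segment_timelapse(sim$timelapse)
  trk <- link_objects(obj, max_displacement = 10)
  smry <- track_summary(trk)
  expect_equal(nrow(smry), 20L)
  expect_true(all(smry$complete))

  # every track stays on one ground-truth cell (no switches)
  truth0 <- sim$truth$trajectories
  for (id in unique(trk$track)) {
    pos <- trk[trk$track == id, ]
    nearest <- vapply(seq_len(nrow(pos)), function(k) {
      cand <- truth0[truth0$frame == pos$frame[k], ]
      cand$cell[which.min((cand$z - pos$z[k])^2 + (cand$y - pos$y[k])^2 +
                            (cand$x - pos$x[k])^2)]
    }, integer(1))
    expect_equal(length(unique(nearest)), 1L)
  }
})

test_that("permuting object ids within frames leaves trajectories unchanged", {
  set.seed(77)
  f1 <- cbind(runif(4, 0, 30), runif(4, 0, 30), runif(4, 0, 30))
  f2 <- f1 + matrix(rnorm(12, 0, 0.5), 4)
  obj <- toy_objects(f1, f2)
  perm <- sample(4)
  obj_p <- obj
  rows2 <- obj_p$frame == 1L
  obj_p[rows2, ] <- obj_p[rows2, ][perm, ]
  obj_p$object[rows2] <- seq_len(4)

  paths <- function(trk) {
    unname(lapply(split(trk[, c("z", "y", "x")], trk$track), as.matrix))
  }
  a <- paths(link_objects(obj, 5))
  b <- paths(link_objects(obj_p, 5))
  key <- function(p) paste(round(p[1, ], 6), collapse = ",")
  expect_setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
})

test_that("track filtering honours length and completeness", {
  obj <- toy_objects(rbind(c(1, 1, 1), c(9, 9, 9)),
                     rbind(c(1, 1, 2), c(9, 9, 10)),
                     rbind(c(1, 1, 3)))
  trk <- link_objects(obj, 3)
  expect_equal(nrow(filter_tracks(trk, min_length = 1)), nrow(trk))
  full <- filter_tracks(trk, min_length = 3)
  expect_equal(length(unique(full$track)), 1L)
  complete <- filter_tracks(trk, require_complete = TRUE)
  expect_equal(length(unique(complete$track)), 1L)
  expect_error(link_objects(obj, max_displacement = 0), "> 0")
})

test_that("retained tracks equal ground-truth visibility under track loss", {
  cfg <- simulation_config(shape = c(24L, 80L, 96L), n_cells = 10,
                           n_frames = 10, drift_per_frame = 0,
                           track_loss_rate = 0.08, active_fraction = 0,
                           seed = 19)
  sim <- generate_timelapse(cfg)
  obj <- segment_timelapse(sim$timelapse)
  trk <- link_objects(obj, max_displacement = 10)
  min_len <- 5L
  kept <- filter_tracks(trk, min_length = min_len)
  visible <- table(sim$truth$trajectories$cell[sim$truth$trajectories$visible])
  expect_equal(length(unique(kept$track)), sum(visible >= min_len))
})
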