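# Moderate-sized scenes keep these loops fast; the full-scale benchmark runs
# in the acceptance suite.

test_that("a clean scene is tracked with detections only and no ID switches", {
  sc <- arena_scene(width = 512, height = 380, n_animals = 3, n_frames = 60,
                    dropout = 0, det_jitter = 0, seed = 31)
  rec <- track_video(function(i) render_frame(sc, i), truth_detector(sc),
                     n_objects = 3, n_frames = 60)
  expect_true(all(rec$source == "detected"))
  expect_equal(count_id_switches(rec, sc$truth), 0)
  expect_equal(as.vector(table(rec$frame)), rep(3L, length(unique(rec$frame))))
})

test_that("a fully suppressed frame is filled from the predictions", {
  sc <- arena_scene(width = 512, height = 380, n_animals = 3, n_frames = 40,
                    dropout = 0, det_jitter = 0, seed = 32)
  base <- truth_detector(sc)
  k <- 25
  det <- function(frame, i) if (i == k) list() else base(frame, i)
  rec <- track_video(function(i) render_frame(sc, i), det,
                     n_objects = 3, n_frames = 40)
  at_k <- rec[rec$frame == k, ]
  expect_equal(nrow(at_k), 3)
  expect_true(all(at_k$source == "filled"))
  tr <- sc$truth[sc$truth$frame == k, ]
  for (r in seq_len(3)) {
    d <- min(sqrt((tr$x - at_k$x[r])^2 + (tr$y - at_k$y[r])^2))
    expect_lt(d, 30)  # within one nine-point grid spacing of the truth
  }
  expect_equal(count_id_switches(rec, sc$truth), 0)
})

test_that("a single animal is tracked trivially", {
  sc <- arena_scene(width = 320, height = 240, n_animals = 1, n_frames = 30,
                    min_separation = 0, seed = 33)
  rec <- track_video(function(i) render_frame(sc, i), truth_detector(sc),
                     n_objects = 1, n_frames = 30)
  expect_equal(unique(rec$track_id), 1L)
  expect_equal(as.vector(table(rec$frame)), rep(1L, length(unique(rec$frame))))
})

test_that("a stream that never shows enough animals raises an error", {
  det <- function(frame, i) list(bbox(0, 0, 10, 10))
  expect_error(
    track_video(function(i) matrix(180, 100, 100), det, n_objects = 3,
                n_frames = 5),
    "never reached"
  )
})

test_that("nine-point correction lowers filled-record error when animals turn", {
  # short dropouts leave the prediction on the (large) body, where the
  # correction rightly keeps it; the correction earns its keep when the
  # detector goes blind for a long stretch while the animal keeps turning,
  # so the constant-velocity extrapolation drifts clear off the body
  sc <- arena_scene(width = 512, height = 380, n_animals = 1, n_frames = 80,
                    heading_jitter = 0.35, speed_range = c(5, 6),
                    dropout = 0, det_jitter = 0, min_separation = 0, seed = 35)
  base <- truth_detector(sc)
  det <- function(frame, i) if (i >= 30 && i <= 55) list() else base(frame, i)
  frames <- function(i) render_frame(sc, i)
  err_filled <- function(rec) {
    f <- rec[rec$source == "filled", ]
    mean(vapply(seq_len(nrow(f)), function(k) {
      tt <- sc$truth[sc$truth$frame == f$frame[k], ]
      min(sqrt((tt$x - f$x[k])^2 + (tt$y - f$y[k])^2))
    }, numeric(1)))
  }
  with_corr <- track_video(frames, det, n_objects = 1, n_frames = 80)
  no_corr <- track_video(frames, det, n_objects = 1, n_frames = 80,
                         config = tracker_config(ninepoint = NULL))
  expect_gt(sum(with_corr$corrected[with_corr$source == "filled"]), 0)
  expect_lt(err_filled(with_corr), err_filled(no_corr))
})

test_that("long-coasting tracks are flagged stale but never dropped", {
  sc <- arena_scene(width = 400, height = 300, n_animals = 2, n_frames = 60,
                    speed_range = c(0.5, 1), dropout = 0, det_jitter = 0,
                    seed = 36)
  base <- truth_detector(sc)
  det <- function(frame, i) {
    d <- base(frame, i)
    if (i >= 10) d[-1] else d  # animal 1 disappears from frame 10 on
  }
  rec <- track_video(function(i) render_frame(sc, i), det, n_objects = 2,
                     n_frames = 60, config = tracker_config(max_coast = 30))
  expect_equal(as.vector(table(rec$frame)), rep(2L, length(unique(rec$frame))))
  lost <- rec[rec$source == "filled" & rec$frame > 45, ]
  expect_true(all(lost$stale == 1))
  early <- rec[rec$source == "filled" & rec$frame < 35, ]
  expect_true(all(early$stale == 0))
})

test_that("exploration map conserves record counts on a 40x30 grid", {
  rec <- data.frame(frame = 1:3, track_id = 1L, x = c(5, 5, 5), y = c(5, 5, 5),
                    source = "detected", corrected = 0L, stale = 0L)
  g <- exploration_map(rec, c(0, 0, 400, 300))
  expect_equal(dim(g), c(30, 40))
  expect_equal(sum(g), 3)
  expect_equal(sum(g > 0), 1)

  set.seed(44)
  walk <- data.frame(frame = 1:1000, track_id = 1L,
                     x = cumsum(rnorm(1000)) %% 400,
                     y = cumsum(rnorm(1000)) %% 300,
                     source = "detected", corrected = 0L, stale = 0L)
  g <- exploration_map(walk, c(0, 0, 400, 300))
  expect_equal(sum(g), 1000)

  bad <- walk; bad$x[7] <- 999
  expect_error(exploration_map(bad, c(0, 0, 400, 300)), "outside the arena")

  # records exactly on cell centers fill the grid uniformly
  cw <- 400 / 40; chh <- 300 / 30
  centers <- expand.grid(x = cw * (0:39) + cw / 2, y = chh * (0:29) + chh / 2)
  unif <- data.frame(frame = seq_len(nrow(centers)), track_id = 1L,
                     x = centers$x, y = centers$y,
                     source = "detected", corrected = 0L, stale = 0L)
  g <- exploration_map(unif, c(0, 0, 400, 300))
  expect_true(all(g == 1))
})

test_that("plot outputs produce non-empty files and a readable CSV", {
  sc <- arena_scene(width = 320, height = 240, n_animals = 3, n_frames = 20,
                    min_separation = 60, seed = 37)
  rec <- track_video(function(i) render_frame(sc, i), truth_detector(sc),
                     n_objects = 3, n_frames = 20)
  dir <- withr::local_tempdir()
  paths <- plot_outputs(rec, exploration_map(rec, c(0, 0, 320, 240)), dir,
                        arena = c(0, 0, 320, 240))
  for (p in paths) {
    expect_true(file.exists(p))
    expect_gt(file.size(p), 0)
  }
  back <- read_tracks_csv(paths["csv"])
  expect_equal(sort(unique(back$track_id)), 1:3)
  expect_equal(nrow(back), nrow(rec))
  expect_error(plot_outputs(rec[0, ], matrix(0, 30, 40), dir), "no records")
})
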