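test_that("cost matrix holds pairwise Euclidean distances", {
  pts <- rbind(c(0, 0), c(3, 4))
  expect_equal(diag(cost_matrix(pts, pts)), c(0, 0))
  expect_equal(cost_matrix(rbind(c(0, 0)), rbind(c(3, 4)))[1, 1], 5)
  set.seed(8)
  a <- matrix(runif(6, 0, 100), 3, 2)
  b <- matrix(runif(6, 0, 100), 3, 2)
  C <- cost_matrix(a, b)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(C[i, j], sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  }
  expect_error(cost_matrix(a, matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("hungarian solver handles the textbook 2x2 cases", {
  p <- solve_assignment(matrix(c(0, 5, 5, 0), 2, 2))
  expect_equal(p[, "col"], c(1, 2))
  p <- solve_assignment(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(p[, "col"], c(2, 1))
  expect_equal(nrow(solve_assignment(matrix(numeric(0), 0, 0))), 0)
  expect_error(solve_assignment(matrix(c(1, Inf, 2, 3), 2, 2)), "finite")
})

test_that("hungarian total cost equals the exhaustive permutation minimum", {
  set.seed(404)
  for (rep in 1:120) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    C <- matrix(round(runif(n * m, 0, 100), 3), n, m)
    p <- solve_assignment(C)
    expect_equal(nrow(p), min(n, m))
    expect_false(anyDuplicated(p[, "row"]) > 0)
    expect_false(anyDuplicated(p[, "col"]) > 0)
    expect_equal(sum(C[p]), brute_assignment_cost(C), tolerance = 1e-9)
  }
})

test_that("associate matches stationary tracks to coincident detections", {
  tracks <- list(track_state(1, 10, 10), track_state(2, 50, 50))
  dets <- rbind(c(10, 10), c(50, 50))
  for (m in c("last_position", "kalman_predicted")) {
    out <- associate(tracks, dets, mode = m)
    expect_equal(out$matches[, "detection"], c(1L, 2L))
    expect_length(out$unmatched_tracks, 0)
  }
})

test_that("rectangular association reports unmatched tracks and detections", {
  tracks <- list(track_state(1, 0, 0), track_state(2, 100, 0),
                 track_state(3, 0, 100))
  out <- associate(tracks, rbind(c(1, 0), c(99, 1)))
  expect_equal(nrow(out$matches), 2)
  expect_equal(out$unmatched_tracks, 3L)
  out <- associate(tracks[1:2], rbind(c(1, 0), c(99, 1), c(500, 500)))
  expect_equal(out$unmatched_detections, 3L)
  # the gate turns an over-distance match into unmatched on both sides
  out <- associate(tracks[1], rbind(c(400, 0)), gate = 150)
  expect_equal(nrow(out$matches), 0)
  expect_equal(out$unmatched_tracks, 1L)
  expect_equal(out$unmatched_detections, 1L)
})

test_that("association is equivariant under detection permutation", {
  set.seed(31)
  tracks <- lapply(1:4, function(k) track_state(k, runif(1, 0, 400), runif(1, 0, 400)))
  dets <- matrix(runif(8, 0, 400), 4, 2)
  base <- associate(tracks, dets)
  perm <- sample(4)
  out <- associate(tracks, dets[perm, ])
  for (r in seq_len(nrow(base$matches))) {
    tr <- base$matches[r, "track"]
    expect_equal(unname(perm[out$matches[out$matches[, "track"] == tr,
                                         "detection"]]),
                 unname(base$matches[r, "detection"]))
  }
})

test_that("kalman-predicted costs keep identities through a crossing", {
  sc <- crossing_scene()
  cf <- attr(sc, "crossing_frame")
  tt <- sc$truth
  pos <- function(f, id) unlist(tt[tt$frame == f & tt$id == id, c("x", "y")])

  # warm two tracks on the exact pre-crossing path
  tracks <- list(track_state(1, pos(1, 1)[1], pos(1, 1)[2]),
                 track_state(2, pos(1, 2)[1], pos(1, 2)[2]))
  exact <- kalman_params(r = c(1e-9, 1e-9))
  for (f in 2:(cf - 1)) {
    for (k in 1:2) {
      tracks[[k]] <- kf_predict(tracks[[k]], 1, exact)
      tracks[[k]] <- kf_update(tracks[[k]], pos(f, k), exact)
    }
  }
  dets <- rbind(pos(cf, 1), pos(cf, 2))
  swapped <- associate(tracks, dets, mode = "last_position")
  expect_equal(swapped$matches[, "detection"], c(2L, 1L))  # the failure mode
  kept <- associate(tracks, dets, mode = "kalman_predicted")
  expect_equal(kept$matches[, "detection"], c(1L, 2L))
})
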