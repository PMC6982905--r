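#' Euclidean cost matrix between track and detection points
#'
#' @param track_points Matrix (n x 2) or list of length-2 points for the
#'   tracks' reference positions.
#' @param detections Matrix (m x 2) or list of points for current-frame
#'   detection centers.
#' @return An n x m matrix of Euclidean distances in pixels.
#' @export
cost_matrix <- function(track_points, detections) {
  a <- as_points(track_points)
  b <- as_points(detections)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both point sets must be non-empty")
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

as_points <- function(p) {
  if (is.matrix(p)) return(p)
  if (is.data.frame(p)) return(as.matrix(p[, 1:2]))
  if (is.list(p)) return(do.call(rbind, lapply(p, function(q) as.numeric(q)[1:2])))
  matrix(as.numeric(p), ncol = 2, byrow = TRUE)
}

#' Minimum-cost bipartite matching (Hungarian algorithm)
#'
#' Solves the rectangular assignment problem by the shortest-augmenting-path
#' form of the Hungarian algorithm (O(n^2 m)): returns a matching of
#' `min(nrow, ncol)` pairs whose total cost is minimal over all such
#' matchings.
#'
#' @param cost Numeric matrix of finite costs; may be rectangular or empty.
#' @return An integer matrix with columns `row` and `col`, one matched pair
#'   per row, ordered by `row`. Empty input gives a 0-row matrix.
#' @export
solve_assignment <- function(cost) {
  if (is.null(cost) || length(cost) == 0 || nrow(cost) == 0 || ncol(cost) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)

  # potentials u (rows), v (cols); p[j] = row matched to column j, 0 if free;
  # column index m + 1 is the virtual start column of each augmentation.
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    way <- integer(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  rows <- p[seq_len(m)]
  pairs <- cbind(row = rows[rows > 0], col = which(rows > 0))
  if (transposed) pairs <- cbind(row = pairs[, "col"], col = pairs[, "row"])
  pairs <- pairs[order(pairs[, "row"]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  pairs
}

#' Associate detections with existing tracks
#'
#' Builds the Euclidean cost between each track's reference point and each
#' detection center, solves the minimum-cost matching, and gates out pairs
#' farther apart than `gate`. In `kalman_predicted` mode (the default and the
#' improvement over plain last-position matching) the reference point is the
#' one-step constant-velocity prediction, which keeps identities through path
#' crossings: when two animals swap neighbourhoods, the predictions land on
#' the correct detections while the previous positions do not. On a fresh
#' track with no velocity estimate the prediction equals the last position,
#' so the two modes coincide until motion information accumulates.
#'
#' @param tracks List of [track_state()] objects.
#' @param detections Detection centers (matrix, list of points, or list of
#'   `bbox` whose centers are taken).
#' @param mode `"kalman_predicted"` (default) or `"last_position"`.
#' @param gate Maximum accepted match distance in pixels (default 150);
#'   costlier pairs are treated as unmatched.
#' @param dt Prediction horizon in frames.
#' @return A list with `matches` (integer matrix, columns `track`,
#'   `detection`), `unmatched_tracks` and `unmatched_detections` (integer
#'   index vectors).
#' @export
associate <- function(tracks, detections,
                      mode = c("kalman_predicted", "last_position"),
                      gate = 150, dt = 1) {
  mode <- match.arg(mode)
  nt <- length(tracks)
  if (length(detections) > 0 && inherits(detections[[1]], "bbox"))
    detections <- lapply(detections, box_center)
  det <- if (length(detections) > 0) as_points(detections)
         else matrix(numeric(0), ncol = 2)
  nd <- nrow(det)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("track", "detection")))
  if (nt == 0 || nd == 0) {
    return(list(matches = empty,
                unmatched_tracks = seq_len(nt),
                unmatched_detections = seq_len(nd)))
  }
  ref <- t(vapply(tracks, function(tr) {
    if (mode == "kalman_predicted") predicted_position(tr, dt)
    else track_position(tr)
  }, numeric(2)))
  cost <- cost_matrix(ref, det)
  pairs <- solve_assignment(cost)
  keep <- cost[pairs] <= gate
  pairs <- pairs[keep, , drop = FALSE]
  colnames(pairs) <- c("track", "detection")
  list(matches = pairs,
       unmatched_tracks = setdiff(seq_len(nt), pairs[, 1]),
       unmatched_detections = setdiff(seq_len(nd), pairs[, 2]))
}
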