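#' Kalman filter noise parameters
#'
#' The per-animal motion model is a linear constant-velocity Kalman filter
#' with state (x, y, vx, vy) in pixels and pixels/frame, observing position
#' only. Process noise defaults give the velocity components more freedom
#' than the positions (the animal changes heading, not teleports); the
#' measurement noise reflects detection jitter of a few pixels.
#'
#' @param q Process noise covariance, 4 x 4 (or a length-4 diagonal).
#'   Default `diag(c(1, 1, 10, 10))` pixels^2.
#' @param r Measurement noise covariance, 2 x 2 (or a length-2 diagonal).
#'   Default `diag(c(10, 10))` pixels^2.
#' @return A list of class `kalman_params`.
#' @export
kalman_params <- function(q = c(1, 1, 10, 10), r = c(10, 10)) {
  if (!is.matrix(q)) q <- diag(q, 4)
  if (!is.matrix(r)) r <- diag(r, 2)
  stopifnot(all(dim(q) == 4), all(dim(r) == 2))
  structure(list(q = q, r = r), class = "kalman_params")
}

#' Per-animal track state
#'
#' Initializes a track from its first detection: position from the
#' measurement, velocity zero, and a covariance that is loose on velocity
#' (`diag(10, 10, 100, 100)`) so the first few updates pin the velocity down.
#'
#' @param id Integer track identity, stable for the life of the track.
#' @param x,y Initial position, pixels.
#' @return An object of class `track_state` with fields `id`, `state`
#'   (length-4 mean), `cov` (4 x 4), `frames_since_detection`, `source_last`.
#' @export
track_state <- function(id, x, y) {
  if (!is.finite(x) || !is.finite(y)) stop("initial position must be finite")
  structure(
    list(id = as.integer(id),
         state = c(x = x, y = y, vx = 0, vy = 0),
         cov = diag(c(10, 10, 100, 100)),
         frames_since_detection = 0L,
         source_last = "detected"),
    class = "track_state"
  )
}

kf_transition <- function(dt) {
  matrix(c(1, 0, 0, 0,
           0, 1, 0, 0,
           dt, 0, 1, 0,
           0, dt, 0, 1), 4, 4)
}

# position-only observation
KF_H <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4)

#' Kalman prediction step
#'
#' Propagates the state mean through the constant-velocity transition
#' (position += velocity * dt, velocity unchanged) and the covariance as
#' `F P F' + Q`.
#'
#' @param track A [track_state()].
#' @param dt Time step in frames, > 0. Default 1.
#' @param params A [kalman_params()].
#' @return The predicted `track_state`.
#' @export
kf_predict <- function(track, dt = 1, params = kalman_params()) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  F <- kf_transition(dt)
  track$state <- drop(F %*% track$state)
  names(track$state) <- c("x", "y", "vx", "vy")
  P <- F %*% track$cov %*% t(F) + params$q
  track$cov <- (P + t(P)) / 2
  track
}

#' Kalman measurement update
#'
#' Standard gain update against a position measurement with observation
#' matrix `H = [[1,0,0,0],[0,1,0,0]]`. The posterior covariance trace never
#' exceeds the prior's.
#'
#' @param track A [track_state()] (normally just predicted).
#' @param measurement Numeric length-2 position `(x, y)`.
#' @param params A [kalman_params()].
#' @return The updated `track_state`.
#' @export
kf_update <- function(track, measurement, params = kalman_params()) {
  z <- as.numeric(measurement)[1:2]
  if (any(!is.finite(z))) stop("measurement must be finite")
  H <- KF_H
  P <- track$cov
  S <- H %*% P %*% t(H) + params$r
  K <- P %*% t(H) %*% solve(S)
  innov <- z - drop(H %*% track$state)
  track$state <- drop(track$state + K %*% innov)
  names(track$state) <- c("x", "y", "vx", "vy")
  # Joseph form keeps the covariance symmetric PSD under roundoff
  A <- diag(4) - K %*% H
  P <- A %*% P %*% t(A) + K %*% params$r %*% t(K)
  track$cov <- (P + t(P)) / 2
  track
}

#' @rdname track_state
#' @param track A `track_state` object.
#' @export
track_position <- function(track) {
  c(x = unname(track$state[1]), y = unname(track$state[2]))
}

#' @rdname track_state
#' @param dt Prediction horizon in frames.
#' @export
predicted_position <- function(track, dt = 1) {
  c(x = unname(track$state[1] + track$state[3] * dt),
    y = unname(track$state[2] + track$state[4] * dt))
}

#' @method print track_state
#' @export
print.track_state <- function(x, ...) {
  cat(sprintf(
    "<track %d: pos (%.1f, %.1f) vel (%.2f, %.2f) %s, %d frame(s) coasting>\n",
    x$id, x$state[1], x$state[2], x$state[3], x$state[4],
    x$source_last, x$frames_since_detection))
  invisible(x)
}
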