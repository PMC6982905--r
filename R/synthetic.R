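#' Synthetic overhead arena scene with ground truth
#'
#' Emulates the recording geometry of an overhead rodent-arena camera: N dark
#' elliptical animals move with approximately constant velocity over a light
#' floor, bouncing off the walls, under additive Gaussian sensor noise,
#' optional salt-and-pepper noise, an optional saturated highlight disk, and
#' per-animal detection dropout (applied to the detection stream, never to
#' the rendering, so filled-track accuracy stays measurable against intact
#' truth). All randomness — trajectories, per-frame noise, dropout, detection
#' jitter — is drawn at construction from `seed`, so the same seed yields
#' bit-identical frames and truth.
#'
#' @param width,height Arena frame size in pixels. Default 1024 x 760, the
#'   resolution of the overhead camera the pipeline targets.
#' @param n_animals Number of animals. Default 3.
#' @param n_frames Number of frames. Default 500.
#' @param floor_gray,body_gray Floor and animal gray levels. Defaults 180
#'   and 60.
#' @param axes Ellipse axis lengths `c(major, minor)` in pixels (full
#'   lengths). Default `c(60, 30)`; the ellipse rotates to follow the
#'   heading.
#' @param speed_range Per-animal speed drawn uniformly from this range,
#'   pixels/frame. Default `c(1, 5)`.
#' @param heading_jitter Standard deviation of the per-frame heading
#'   perturbation in radians; 0 (default) gives exactly constant velocity
#'   between wall bounces.
#' @param noise_sigma Gaussian sensor noise standard deviation, gray levels.
#'   Default 2.
#' @param sp_density Salt-and-pepper pixel fraction. Default 0.005.
#' @param dropout Per-animal, per-frame probability that the detection
#'   stream misses the animal. Default 0.
#' @param det_jitter Detection center noise standard deviation, pixels.
#'   Default 1.
#' @param highlight Optional saturated disk, `list(center = c(x, y),
#'   radius = r)`, rendered at gray 255.
#' @param min_separation Minimum initial center separation, pixels.
#'   Default 120.
#' @param seed Integer seed; part of the scene's identity.
#' @return An object of class `arena_scene` carrying the truth table
#'   (`$truth`: frame, id, x, y, vx, vy) and everything needed to render any
#'   frame with [render_frame()].
#' @export
arena_scene <- function(width = 1024, height = 760, n_animals = 3,
                        n_frames = 500, floor_gray = 180, body_gray = 60,
                        axes = c(60, 30), speed_range = c(1, 5),
                        heading_jitter = 0, noise_sigma = 2,
                        sp_density = 0.005, dropout = 0, det_jitter = 1,
                        highlight = NULL, min_separation = 120, seed = 1) {
  a <- axes[1] / 2
  if (2 * a >= min(width, height))
    stop("animals larger than the arena")
  if (n_animals < 1 || n_frames < 1) stop("need at least one animal and frame")
  scene <- structure(
    list(width = width, height = height, n_animals = n_animals,
         n_frames = n_frames, floor_gray = floor_gray, body_gray = body_gray,
         axes = axes, speed_range = speed_range,
         heading_jitter = heading_jitter, noise_sigma = noise_sigma,
         sp_density = sp_density, dropout = dropout, det_jitter = det_jitter,
         highlight = highlight, min_separation = min_separation, seed = seed),
    class = "arena_scene"
  )
  with_seed(seed, {
    scene$truth <- simulate_truth(scene)
    scene$noise_seeds <- sample.int(.Machine$integer.max, n_frames)
    scene$det_keep <- matrix(stats::runif(n_frames * n_animals) >= dropout,
                             n_frames, n_animals)
    scene$det_jx <- matrix(stats::rnorm(n_frames * n_animals, 0, det_jitter),
                           n_frames, n_animals)
    scene$det_jy <- matrix(stats::rnorm(n_frames * n_animals, 0, det_jitter),
                           n_frames, n_animals)
  })
  scene
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

simulate_truth <- function(scene) {
  margin <- scene$axes[1] / 2 + 2
  w <- scene$width; h <- scene$height; n <- scene$n_animals
  # initial positions by rejection sampling on pairwise separation
  pos <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    for (attempt in 1:1000) {
      p <- c(stats::runif(1, margin, w - 1 - margin),
             stats::runif(1, margin, h - 1 - margin))
      if (i == 1 || all(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2)) >=
                          scene$min_separation)) {
        pos[i, ] <- p
        break
      }
      if (attempt == 1000) stop("could not place animals with the requested separation")
    }
  }
  speed <- stats::runif(n, scene$speed_range[1], scene$speed_range[2])
  theta <- stats::runif(n, 0, 2 * pi)
  vel <- cbind(speed * cos(theta), speed * sin(theta))
  rows <- vector("list", scene$n_frames)
  for (t in seq_len(scene$n_frames)) {
    rows[[t]] <- data.frame(frame = t, id = seq_len(n),
                            x = pos[, 1], y = pos[, 2],
                            vx = vel[, 1], vy = vel[, 2])
    if (scene$heading_jitter > 0) {
      dth <- stats::rnorm(n, 0, scene$heading_jitter)
      vel <- cbind(vel[, 1] * cos(dth) - vel[, 2] * sin(dth),
                   vel[, 1] * sin(dth) + vel[, 2] * cos(dth))
    }
    pos <- pos + vel
    # keep animals apart: approaching pairs closer than min_separation
    # exchange the velocity components along their center line (equal-mass
    # elastic bounce), so blobs never merge outside designed crossing scenes
    if (n > 1 && scene$min_separation > 0) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- pos[j, ] - pos[i, ]
        dist <- sqrt(sum(d^2))
        if (dist > 0 && dist < scene$min_separation) {
          u <- d / dist
          rel <- sum((vel[j, ] - vel[i, ]) * u)
          if (rel < 0) {  # approaching
            vel[i, ] <- vel[i, ] + rel * u
            vel[j, ] <- vel[j, ] - rel * u
          }
        }
      }
    }
    # reflective walls
    for (i in seq_len(n)) {
      if (pos[i, 1] < margin) { pos[i, 1] <- 2 * margin - pos[i, 1]; vel[i, 1] <- -vel[i, 1] }
      if (pos[i, 1] > w - 1 - margin) { pos[i, 1] <- 2 * (w - 1 - margin) - pos[i, 1]; vel[i, 1] <- -vel[i, 1] }
      if (pos[i, 2] < margin) { pos[i, 2] <- 2 * margin - pos[i, 2]; vel[i, 2] <- -vel[i, 2] }
      if (pos[i, 2] > h - 1 - margin) { pos[i, 2] <- 2 * (h - 1 - margin) - pos[i, 2]; vel[i, 2] <- -vel[i, 2] }
    }
  }
  do.call(rbind, rows)
}

#' Render one frame of a synthetic scene
#'
#' @param scene An [arena_scene()].
#' @param i Frame index, 1-based.
#' @return An 8-bit grayscale matrix (0..255 integers stored as numeric).
#' @export
render_frame <- function(scene, i) {
  if (i < 1 || i > scene$n_frames) stop("frame index out of range")
  tr <- scene$truth[scene$truth$frame == i, ]
  img <- matrix(scene$floor_gray, scene$height, scene$width)
  a <- scene$axes[1] / 2; b <- scene$axes[2] / 2
  for (k in seq_len(nrow(tr))) {
    img <- draw_ellipse(img, tr$x[k], tr$y[k],
                        atan2(tr$vy[k], tr$vx[k]), a, b, scene$body_gray)
  }
  if (!is.null(scene$highlight)) {
    hc <- scene$highlight$center; hr <- scene$highlight$radius
    xs <- max(1, ceiling(hc[1] - hr)):min(scene$width - 1, floor(hc[1] + hr)) + 1
    ys <- max(1, ceiling(hc[2] - hr)):min(scene$height - 1, floor(hc[2] + hr)) + 1
    dx2 <- outer(ys - 1 - hc[2], xs - 1 - hc[1], function(yy, xx) xx^2 + yy^2)
    sub <- img[ys, xs]
    sub[dx2 <= hr^2] <- 255
    img[ys, xs] <- sub
  }
  if (scene$noise_sigma > 0 || scene$sp_density > 0) {
    img <- with_seed(scene$noise_seeds[i], {
      if (scene$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, scene$noise_sigma),
                            nrow(img))
      if (scene$sp_density > 0) {
        nsp <- round(scene$sp_density * length(img))
        if (nsp > 0) {
          at <- sample.int(length(img), nsp)
          img[at] <- sample(c(0, 255), nsp, replace = TRUE)
        }
      }
      img
    })
  }
  round(pmin(pmax(img, 0), 255))
}

draw_ellipse <- function(img, cx, cy, theta, a, b, gray) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(0, floor(cx - a)):min(w - 1, ceiling(cx + a))
  ys <- max(0, floor(cy - a)):min(h - 1, ceiling(cy + a))
  ct <- cos(theta); st <- sin(theta)
  X <- outer(rep(1, length(ys)), xs) - cx
  Y <- outer(ys, rep(1, length(xs))) - cy
  U <- X * ct + Y * st
  V <- -X * st + Y * ct
  inside <- (U / a)^2 + (V / b)^2 <= 1
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- gray
  img[ys + 1, xs + 1] <- sub
  img
}

#' Axis-aligned true bounding box of an animal
#'
#' @param x,y,vx,vy A truth row: center and velocity (heading).
#' @param axes Ellipse axis lengths, as in [arena_scene()].
#' @return A `bbox` enclosing the rotated ellipse.
#' @export
true_bbox <- function(x, y, vx, vy, axes = c(60, 30)) {
  a <- axes[1] / 2; b <- axes[2] / 2
  th <- atan2(vy, vx)
  hw <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hh <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  bbox(floor(x - hw), floor(y - hh), ceiling(x + hw), ceiling(y + hh))
}

#' Materialize a scene as a frame stream plus truth table
#'
#' @param scene An [arena_scene()].
#' @param out_dir Optional directory; when given, frames are written as
#'   numbered PNG files together with `truth.csv` (requires the `png`
#'   package).
#' @return A list with `frame` (function of the frame index), `n_frames`,
#'   and `truth`.
#' @export
generate_scene <- function(scene, out_dir = NULL) {
  stopifnot(inherits(scene, "arena_scene"))
  if (!is.null(out_dir)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG frames requires the 'png' package")
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_len(scene$n_frames)) {
      png::writePNG(render_frame(scene, i) / 255,
                    file.path(out_dir, sprintf("frame_%06d.png", i)))
    }
    utils::write.csv(scene$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(frame = function(i) render_frame(scene, i),
       n_frames = scene$n_frames, truth = scene$truth)
}

#' Truth-based detector with dropout
#'
#' Turns the scene's ground truth into a detection stream: each animal's true
#' bounding box is emitted with probability `1 - dropout`, its center
#' perturbed by the scene's detection jitter. Dropout and jitter draws were
#' fixed at scene construction, so the stream is deterministic. This is the
#' stand-in for an external trained detector when studying the tracking
#' stages in isolation.
#'
#' @param scene An [arena_scene()].
#' @return A detector `function(frame, i)` returning a list of `bbox`,
#'   usable with [track_video()].
#' @export
truth_detector <- function(scene) {
  force(scene)
  function(frame, i) {
    tr <- scene$truth[scene$truth$frame == i, ]
    out <- list()
    for (k in seq_len(nrow(tr))) {
      if (!scene$det_keep[i, tr$id[k]]) next
      bb <- true_bbox(tr$x[k] + scene$det_jx[i, tr$id[k]],
                      tr$y[k] + scene$det_jy[i, tr$id[k]],
                      tr$vx[k], tr$vy[k], scene$axes)
      bb$xmin <- max(0, bb$xmin); bb$ymin <- max(0, bb$ymin)
      bb$xmax <- min(scene$width, bb$xmax); bb$ymax <- min(scene$height, bb$ymax)
      out[[length(out) + 1L]] <- bb
    }
    out
  }
}

#' Designed path-crossing scene
#'
#' Two animals approach head-on with a small lateral offset and pass between
#' two frames, so that at the frame right after the pass each detection lies
#' nearer the OTHER track's previous position — the configuration that makes
#' plain last-position matching swap identities while matching against
#' Kalman-predicted positions does not.
#'
#' @param speed Approach speed, pixels/frame. Default 40.
#' @param offset Lateral offset between the two straight paths, pixels.
#'   Default 4.
#' @param n_frames Scene length. Default 12.
#' @return An [arena_scene()] whose `crossing_frame` attribute marks the
#'   frame immediately after the pass.
#' @export
crossing_scene <- function(speed = 40, offset = 4, n_frames = 12) {
  scene <- arena_scene(n_animals = 2, n_frames = n_frames, noise_sigma = 0,
                       sp_density = 0, dropout = 0, det_jitter = 0, seed = 7)
  y0 <- 380 - offset / 2
  y1 <- 380 + offset / 2
  t <- seq_len(n_frames) - 1
  scene$truth <- rbind(
    data.frame(frame = seq_len(n_frames), id = 1L,
               x = 300 + speed * t, y = y0, vx = speed, vy = 0),
    data.frame(frame = seq_len(n_frames), id = 2L,
               x = 680 - speed * t, y = y1, vx = -speed, vy = 0)
  )
  scene$truth <- scene$truth[order(scene$truth$frame, scene$truth$id), ]
  # pass happens where 300 + s*t = 680 - s*t
  attr(scene, "crossing_frame") <- ceiling((680 - 300) / (2 * speed)) + 1L
  scene
}
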