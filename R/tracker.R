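#' Tracker configuration
#'
#' Bundles the tunables of the full pipeline: NMS threshold, association mode
#' and gate, Kalman noise, nine-point correction parameters, and how long a
#' track may coast on predictions before being flagged stale.
#'
#' @param nms_threshold IOU above which overlapping detections are
#'   suppressed. Default 0.45.
#' @param mode Association mode, `"kalman_predicted"` (default) or
#'   `"last_position"`; see [associate()].
#' @param gate Maximum track-to-detection match distance, pixels. Default
#'   150.
#' @param kalman A [kalman_params()] object.
#' @param ninepoint A [ninepoint_params()] object, or `NULL` to disable the
#'   nine-point correction.
#' @param max_coast Consecutive filled frames after which a track is flagged
#'   stale in the output (it is never deleted — the animal count is fixed).
#'   Default 30.
#' @param verbose Log per-frame detection counts with [message()].
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(nms_threshold = 0.45,
                           mode = c("kalman_predicted", "last_position"),
                           gate = 150,
                           kalman = kalman_params(),
                           ninepoint = ninepoint_params(),
                           max_coast = 30,
                           verbose = FALSE) {
  structure(list(nms_threshold = nms_threshold, mode = match.arg(mode),
                 gate = gate, kalman = kalman, ninepoint = ninepoint,
                 max_coast = max_coast, verbose = verbose),
            class = "tracker_config")
}

#' Track a fixed number of animals through a frame stream
#'
#' The frame loop: detect -> non-maximum suppression -> assign detections to
#' track identities (Hungarian matching on Kalman-predicted positions) ->
#' Kalman update of matched tracks -> fill unmatched tracks with their
#' prediction -> nine-point gray-value correction of every reported position.
#' Tracks are created on the first frame in which at least `n_objects`
#' detections survive NMS (earlier frames yield no records); from then on
#' exactly `n_objects` records are emitted per frame, each tagged with its
#' provenance: `source = "detected"` when backed by a detection, `"filled"`
#' when supplied by the motion model, and `corrected = 1` when the nine-point
#' correction moved the point. Surplus detections that match no track within
#' the gate are dropped.
#'
#' @param frames A list of frames or a function `frames(i)` returning frame
#'   `i` (frames are only rendered/fetched when needed for the nine-point
#'   correction or for a detector that consumes pixels).
#' @param detector `function(frame, i)` returning a list of `bbox`; defaults
#'   to the classical segmentation detector [detect_blobs()].
#' @param n_objects Known number of animals in the arena.
#' @param n_frames Number of frames when `frames` is a function.
#' @param config A [tracker_config()].
#' @param seg A [seg_params()] object for the default detector.
#' @return A data frame of records (frame, track_id, x, y, source, corrected,
#'   stale) with attribute `detection_tally`: the per-frame detection-count
#'   tally (how many frames had 0, 1, ..., n, > n detections) and the share
#'   of frames with all animals reported after filling.
#' @export
track_video <- function(frames, detector = NULL, n_objects,
                        n_frames = length(frames),
                        config = tracker_config(), seg = seg_params()) {
  if (n_objects < 1) stop("n_objects must be >= 1")
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  if (is.null(detector))
    detector <- function(frame, i) detect_blobs(frame, seg)
  needs_pixels <- !is.null(config$ninepoint)

  tracks <- NULL
  recs <- vector("list", n_frames)
  tally <- integer(n_objects + 2)  # counts of frames with 0..n, >n detections
  names(tally) <- c(as.character(0:n_objects), paste0(">", n_objects))

  for (i in seq_len(n_frames)) {
    frame <- NULL
    fetch <- function() {
      if (is.null(frame)) frame <<- get_frame(i)
      frame
    }
    dets <- detector(fetch(), i)
    dets <- nms(dets, config$nms_threshold)
    nd <- length(dets)
    tally[min(nd, n_objects + 1) + 1L] <- tally[min(nd, n_objects + 1) + 1L] + 1L
    if (config$verbose)
      message(sprintf("frame %d: %d detection(s)%s", i, nd,
                      if (is.null(tracks)) " [awaiting initialization]" else ""))
    centers <- lapply(dets, box_center)

    if (is.null(tracks)) {
      if (nd >= n_objects) {
        # initialize from the n_objects highest-scoring detections (NMS
        # already sorted by descending score)
        tracks <- lapply(seq_len(n_objects), function(k) {
          p <- centers[[k]]
          track_state(k, p[1], p[2])
        })
        recs[[i]] <- record_frame(i, tracks, rep("detected", n_objects),
                                  rep(FALSE, n_objects), config)
      }
      next
    }

    asn <- associate(tracks, centers, mode = config$mode, gate = config$gate)
    source <- character(n_objects)
    pos <- matrix(NA_real_, n_objects, 2)
    for (k in seq_len(n_objects)) tracks[[k]] <- kf_predict(tracks[[k]], 1, config$kalman)
    if (nrow(asn$matches) > 0) {
      for (r in seq_len(nrow(asn$matches))) {
        ti <- asn$matches[r, "track"]; di <- asn$matches[r, "detection"]
        meas <- centers[[di]]
        if (needs_pixels) {
          cp <- correct_position(fetch(), meas, config$ninepoint)
          meas <- cp$point
        }
        tracks[[ti]] <- kf_update(tracks[[ti]], meas, config$kalman)
        tracks[[ti]]$frames_since_detection <- 0L
        tracks[[ti]]$source_last <- "detected"
        source[ti] <- "detected"
        pos[ti, ] <- meas
      }
    }
    corrected <- rep(FALSE, n_objects)
    for (ti in asn$unmatched_tracks) {
      p <- track_position(tracks[[ti]])  # already predicted
      if (needs_pixels) {
        cp <- correct_position(fetch(), p, config$ninepoint)
        if (cp$status == "corrected") corrected[ti] <- TRUE
        p <- cp$point
      }
      tracks[[ti]]$frames_since_detection <-
        tracks[[ti]]$frames_since_detection + 1L
      tracks[[ti]]$source_last <- "filled"
      source[ti] <- "filled"
      pos[ti, ] <- p
    }
    # detected positions may have been nine-point corrected too
    if (nrow(asn$matches) > 0 && needs_pixels) {
      for (r in seq_len(nrow(asn$matches))) {
        ti <- asn$matches[r, "track"]
        orig <- box_center(dets[[asn$matches[r, "detection"]]])
        if (any(abs(pos[ti, ] - orig) > 1e-9)) corrected[ti] <- TRUE
      }
    }
    recs[[i]] <- data.frame(
      frame = i,
      track_id = vapply(tracks, function(tr) tr$id, integer(1)),
      x = pos[, 1], y = pos[, 2],
      source = source, corrected = as.integer(corrected),
      stale = as.integer(vapply(tracks, function(tr)
        tr$frames_since_detection, integer(1)) > config$max_coast)
    )
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    stop("the stream never reached ", n_objects,
         " simultaneous detections; tracks were never initialized")
  rownames(out) <- NULL
  full <- tapply(out$track_id, out$frame, length)
  attr(out, "detection_tally") <- tally
  attr(out, "full_frame_share") <- mean(full == n_objects)
  if (config$verbose) {
    message("detection tally (frames by detection count): ",
            paste(names(tally), tally, sep = "=", collapse = ", "))
    message(sprintf("frames with all %d positions after filling: %.3f%%",
                    n_objects, 100 * mean(full == n_objects)))
  }
  out
}

record_frame <- function(i, tracks, source, corrected, config) {
  data.frame(
    frame = i,
    track_id = vapply(tracks, function(tr) tr$id, integer(1)),
    x = vapply(tracks, function(tr) unname(tr$state[1]), numeric(1)),
    y = vapply(tracks, function(tr) unname(tr$state[2]), numeric(1)),
    source = source, corrected = as.integer(corrected),
    stale = 0L
  )
}

#' Bin tracked positions into an exploration grid
#'
#' Divides the arena into `n_cols` x `n_rows` rectangular cells (default
#' 40 x 30) and counts, per cell, the number of (frame, position) records
#' falling in it — the duration-of-stay map of the arena.
#'
#' @param records Data frame from [track_video()].
#' @param arena Rectangle `c(xmin, ymin, xmax, ymax)` enclosing all
#'   positions.
#' @param n_cols,n_rows Grid size. Defaults 40 and 30.
#' @return An `n_rows` x `n_cols` integer matrix of counts summing to
#'   `nrow(records)`.
#' @export
exploration_map <- function(records, arena, n_cols = 40, n_rows = 30) {
  if (nrow(records) == 0) stop("no records to bin")
  out_of <- records$x < arena[1] | records$x > arena[3] |
            records$y < arena[2] | records$y > arena[4]
  if (any(out_of)) {
    k <- which(out_of)[1]
    stop(sprintf("record (frame %d, track %d) lies outside the arena",
                 records$frame[k], records$track_id[k]))
  }
  cw <- (arena[3] - arena[1]) / n_cols
  ch <- (arena[4] - arena[2]) / n_rows
  cx <- pmin(floor((records$x - arena[1]) / cw), n_cols - 1)
  cy <- pmin(floor((records$y - arena[2]) / ch), n_rows - 1)
  grid <- matrix(0L, n_rows, n_cols)
  for (k in seq_along(cx))
    grid[cy[k] + 1, cx[k] + 1] <- grid[cy[k] + 1, cx[k] + 1] + 1L
  grid
}

#' Write trajectory plot, exploration heatmap, and CSV
#'
#' @param records Data frame from [track_video()].
#' @param grid Matrix from [exploration_map()].
#' @param out_dir Output directory; receives `trajectory.png`,
#'   `exploration.png`, and `tracks.csv`.
#' @param arena Arena rectangle for axis limits.
#' @return Invisibly, the paths written.
#' @export
plot_outputs <- function(records, grid, out_dir,
                         arena = c(0, 0, max(records$x), max(records$y))) {
  if (is.null(records) || nrow(records) == 0) stop("no records to plot")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  traj <- file.path(out_dir, "trajectory.png")
  heat <- file.path(out_dir, "exploration.png")
  csv <- file.path(out_dir, "tracks.csv")

  grDevices::png(traj, width = 800, height = 600)
  graphics::plot(NA, xlim = c(arena[1], arena[3]), ylim = c(arena[4], arena[2]),
                 xlab = "x (px)", ylab = "y (px)", main = "Trajectories",
                 asp = 1)
  ids <- sort(unique(records$track_id))
  for (k in seq_along(ids)) {
    r <- records[records$track_id == ids[k], ]
    r <- r[order(r$frame), ]
    graphics::lines(r$x, r$y, col = k + 1, lwd = 1.5)
  }
  graphics::legend("topright", legend = paste("track", ids),
                   col = seq_along(ids) + 1, lwd = 1.5, bty = "n")
  grDevices::dev.off()

  grDevices::png(heat, width = 800, height = 600)
  graphics::image(t(grid)[, nrow(grid):1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, main = "Exploration (frames per cell)")
  grDevices::dev.off()

  write_tracks_csv(records, csv)
  invisible(c(trajectory = traj, heatmap = heat, csv = csv))
}

#' Count identity switches against ground truth
#'
#' Maps each record to the nearest true animal in its frame and counts, per
#' track, how often that mapping changes between consecutive frames — the
#' standard ID-switch tally of tracking evaluation.
#'
#' @param records Data frame from [track_video()].
#' @param truth Truth table with columns frame, id, x, y.
#' @return Integer number of switches.
#' @export
count_id_switches <- function(records, truth) {
  switches <- 0L
  for (tid in unique(records$track_id)) {
    r <- records[records$track_id == tid, ]
    r <- r[order(r$frame), ]
    mapped <- vapply(seq_len(nrow(r)), function(k) {
      tf <- truth[truth$frame == r$frame[k], ]
      tf$id[which.min((tf$x - r$x[k])^2 + (tf$y - r$y[k])^2)]
    }, numeric(1))
    switches <- switches + sum(diff(mapped) != 0)
  }
  switches
}
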