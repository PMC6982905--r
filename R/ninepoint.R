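#' Parameters of the nine-point position correction
#'
#' A claimed animal position (from the detector or from the Kalman
#' prediction) is verified against the gray image: the point and the eight
#' surrounding points of a 3 x 3 grid are probed, and if the center does not
#' lie on the animal's body the position is snapped to the best qualifying
#' grid point.
#'
#' @param spacing Grid step in pixels between neighbouring probe points.
#'   Default 30.
#' @param gray_threshold Gray level separating body from floor; a probe with
#'   gray strictly below it counts as body under `dark_object`. Default 105.
#' @param polarity `"dark_object"` (default; animal darker than floor) or
#'   `"light_object"`.
#' @param patch_radius Radius of the square patch averaged at each probe;
#'   0 (default) samples the single pixel.
#' @return A list of class `ninepoint_params`.
#' @export
ninepoint_params <- function(spacing = 30, gray_threshold = 105,
                             polarity = c("dark_object", "light_object"),
                             patch_radius = 0) {
  if (spacing < 0) stop("spacing must be >= 0")
  if (gray_threshold < 0 || gray_threshold > 255)
    stop("gray_threshold must lie in [0, 255]")
  structure(list(spacing = spacing, gray_threshold = gray_threshold,
                 polarity = match.arg(polarity), patch_radius = patch_radius),
            class = "ninepoint_params")
}

#' The nine probe points around a center
#'
#' Returns the center plus the eight points of a 3 x 3 grid at offsets
#' `{-spacing, 0, +spacing}` in x and y, in row-major scan order with the
#' center first. When image `bounds = c(width, height)` are supplied,
#' off-image points are clipped to the border, keeping the candidate count at
#' nine.
#'
#' @param center Numeric length-2 point `(x, y)`.
#' @param spacing Grid step, pixels.
#' @param bounds Optional `c(width, height)` of the image.
#' @return A 9 x 2 matrix of points, the first row being the center.
#' @export
nine_points <- function(center, spacing = 30, bounds = NULL) {
  center <- as.numeric(center)[1:2]
  if (any(!is.finite(center))) stop("center must be finite")
  off <- c(-spacing, 0, spacing)
  grid <- as.matrix(expand.grid(dx = off, dy = off))
  pts <- cbind(x = center[1] + grid[, 1], y = center[2] + grid[, 2])
  ctr <- which(grid[, 1] == 0 & grid[, 2] == 0)[1]
  pts <- rbind(pts[ctr, , drop = FALSE], pts[-ctr, , drop = FALSE])
  if (!is.null(bounds)) {
    pts[, 1] <- pmin(pmax(pts[, 1], 0), bounds[1] - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), bounds[2] - 1)
  }
  pts
}

#' Nine-point gray-value position correction
#'
#' Checks whether the claimed position lies on the animal's body (gray value
#' strictly below the threshold for a dark animal). If it does, the point is
#' returned unchanged with status `"kept"`. Otherwise each of the nine grid
#' points is probed; among the qualifying ones the point with the minimum
#' (for `dark_object`) gray value is returned with status `"corrected"`,
#' ties broken by distance to the center and then by scan order. If no point
#' qualifies, the original center is returned with status `"failed"`.
#'
#' @param gray Grayscale image matrix, 0..255.
#' @param center Claimed position `(x, y)` inside the image.
#' @param params A [ninepoint_params()] object.
#' @return A list with `point` (length-2 named numeric) and `status` (one of
#'   `"kept"`, `"corrected"`, `"failed"`).
#' @export
correct_position <- function(gray, center, params = ninepoint_params()) {
  check_frame(gray)
  if (is_color(gray)) gray <- to_gray(gray)
  h <- img_height(gray); w <- img_width(gray)
  center <- as.numeric(center)[1:2]
  center[1] <- min(max(center[1], 0), w - 1)
  center[2] <- min(max(center[2], 0), h - 1)
  is_body <- function(g) {
    if (params$polarity == "dark_object") g < params$gray_threshold
    else g > params$gray_threshold
  }
  g0 <- sample_gray(gray, center[1], center[2], params$patch_radius)
  if (is_body(g0))
    return(list(point = c(x = center[1], y = center[2]), status = "kept"))
  pts <- nine_points(center, params$spacing, bounds = c(w, h))
  gv <- vapply(seq_len(nrow(pts)), function(i)
    sample_gray(gray, pts[i, 1], pts[i, 2], params$patch_radius), numeric(1))
  ok <- is_body(gv)
  if (!any(ok))
    return(list(point = c(x = center[1], y = center[2]), status = "failed"))
  cand <- which(ok)
  key <- if (params$polarity == "dark_object") gv[cand] else -gv[cand]
  d2 <- (pts[cand, 1] - center[1])^2 + (pts[cand, 2] - center[2])^2
  best <- cand[order(key, d2, cand)[1]]
  list(point = c(x = unname(pts[best, 1]), y = unname(pts[best, 2])),
       status = "corrected")
}
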