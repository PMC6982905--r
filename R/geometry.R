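#' Axis-aligned scored bounding box
#'
#' Boxes use a 0-based, half-open pixel convention: a box
#' `(xmin, ymin, xmax, ymax)` covers pixel columns `xmin .. xmax - 1` and rows
#' `ymin .. ymax - 1` (origin at the top-left corner, x rightwards, y
#' downwards), so its area is `(xmax - xmin) * (ymax - ymin)`. The same
#' convention is used everywhere in the package, including PASCAL VOC export
#' (which converts to the format's 1-based inclusive coordinates on write).
#'
#' @param xmin,ymin,xmax,ymax Pixel coordinates; `xmin < xmax`, `ymin < ymax`.
#' @param score Detector confidence in `[0, 1]`.
#' @param label Class label string.
#' @return An object of class `bbox`.
#' @examples
#' b <- bbox(0, 0, 10, 10, score = 0.9)
#' box_area(b)
#' @export
bbox <- function(xmin, ymin, xmax, ymax, score = 1, label = "rat") {
  vals <- c(xmin, ymin, xmax, ymax, score)
  if (any(!is.finite(vals))) stop("bbox coordinates and score must be finite")
  if (xmin >= xmax || ymin >= ymax)
    stop("degenerate box: need xmin < xmax and ymin < ymax")
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  structure(
    list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
         score = score, label = label),
    class = "bbox"
  )
}

#' @method print bbox
#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%g, %g, %g, %g] score=%.3f label=%s>\n",
              x$xmin, x$ymin, x$xmax, x$ymax, x$score, x$label))
  invisible(x)
}

#' @rdname bbox
#' @param box A `bbox` object.
#' @export
box_area <- function(box) {
  (box$xmax - box$xmin) * (box$ymax - box$ymin)
}

#' @rdname bbox
#' @export
box_center <- function(box) {
  c(x = (box$xmin + box$xmax) / 2, y = (box$ymin + box$ymax) / 2)
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  stop("expected a bbox object")
}

#' Intersection over union of two boxes
#'
#' The overlap metric used both for non-maximum suppression and for
#' detection-vs-truth evaluation: the area of the intersection of two boxes
#' divided by the area of their union.
#'
#' @param a,b `bbox` objects with positive area.
#' @return A ratio in `[0, 1]`; 0 when the boxes are disjoint, 1 when
#'   identical. Symmetric in its arguments.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10)) # 50 / 150
#' @export
iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  ix <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  iy <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  inter <- max(0, ix) * max(0, iy)
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Non-maximum suppression
#'
#' Greedy suppression of overlapping detections: boxes are sorted by
#' descending score, the best box of each overlap cluster is kept, and any
#' remaining box whose IOU with a kept box exceeds `iou_threshold` is
#' deleted. Ties in score are broken by input order (stable sort), so the
#' result is deterministic.
#'
#' @param boxes A list of `bbox` objects (may be empty).
#' @param iou_threshold Overlap above which the lower-scored box is removed;
#'   must lie strictly in (0, 1). Default 0.45.
#' @return The surviving boxes, sorted by descending score. Idempotent: a
#'   second pass changes nothing.
#' @export
nms <- function(boxes, iou_threshold = 0.45) {
  if (length(boxes) == 0) return(list())
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie strictly between 0 and 1")
  boxes <- lapply(boxes, as_bbox)
  scores <- vapply(boxes, function(b) b$score, numeric(1))
  ord <- order(-scores)                      # stable: ties keep input order
  keep <- list()
  alive <- rep(TRUE, length(boxes))
  for (i in ord) {
    if (!alive[i]) next
    keep[[length(keep) + 1L]] <- boxes[[i]]
    alive[i] <- FALSE
    for (j in ord) {
      if (alive[j] && iou(boxes[[i]], boxes[[j]]) > iou_threshold)
        alive[j] <- FALSE
    }
  }
  keep
}
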