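# Fixtures and independent oracles used across the suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# A flat frame with axis-aligned (theta = 0) ellipses drawn on it.
ellipse_frame <- function(width, height, centers, axes = c(60, 30),
                          floor_gray = 180, body_gray = 60) {
  img <- matrix(floor_gray, height, width)
  a <- axes[1] / 2
  b <- axes[2] / 2
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    xs <- max(0, floor(cx - a)):min(width - 1, ceiling(cx + a))
    ys <- max(0, floor(cy - b)):min(height - 1, ceiling(cy + b))
    for (x in xs) for (y in ys) {
      if (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1) img[y + 1, x + 1] <- body_gray
    }
  }
  img
}

random_boxes <- function(n, width = 200, height = 200, max_side = 60) {
  lapply(seq_len(n), function(i) {
    x0 <- runif(1, 0, width - max_side)
    y0 <- runif(1, 0, height - max_side)
    bbox(round(x0), round(y0),
         round(x0 + runif(1, 5, max_side)), round(y0 + runif(1, 5, max_side)),
         score = round(runif(1), 3))
  })
}

# Independent greedy NMS oracle: repeatedly take the highest-scoring
# remaining box (first on ties) and delete everything overlapping it beyond
# the threshold. Written over a plain data frame, unlike nms().
nms_oracle <- function(boxes, thr) {
  df <- data.frame(
    i = seq_along(boxes),
    score = vapply(boxes, function(b) b$score, numeric(1))
  )
  kept <- integer(0)
  while (nrow(df) > 0) {
    best <- df$i[which.max(df$score)]   # which.max takes the first max: stable
    kept <- c(kept, best)
    ious <- vapply(df$i, function(j) iou(boxes[[best]], boxes[[j]]), numeric(1))
    df <- df[ious <= thr, , drop = FALSE]
  }
  kept
}

# All permutations of 1..n (exhaustive matching oracle).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    m <- cbind(k, sub + (sub >= k))
    out <- rbind(out, m)
  }
  out
}

# Exhaustive minimum-cost matching for small (possibly rectangular) matrices.
brute_assignment_cost <- function(cost) {
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  cols <- utils::combn(m, n, simplify = FALSE)
  best <- Inf
  perms <- all_perms(n)
  for (cc in cols) {
    for (p in seq_len(nrow(perms))) {
      tot <- sum(cost[cbind(seq_len(n), cc[perms[p, ]])])
      if (tot < best) best <- tot
    }
  }
  best
}

# Highlight fixture: saturated disk on a dark floor, with the mask around it.
highlight_fixture <- function(floor_gray = 120, h = 120, w = 140,
                              disk = c(70, 60, 10), mask_box = c(50, 40, 90, 80)) {
  img <- matrix(floor_gray, h, w)
  for (x in 0:(w - 1)) for (y in 0:(h - 1)) {
    if ((x - disk[1])^2 + (y - disk[2])^2 <= disk[3]^2) img[y + 1, x + 1] <- 255
  }
  mask <- matrix(FALSE, h, w)
  mask[(mask_box[2]:mask_box[4]) + 1, (mask_box[1]:mask_box[3]) + 1] <- TRUE
  list(img = img, mask = mask)
}

recall_at_iou <- function(detected, truth_boxes, thr = 0.5) {
  if (length(truth_boxes) == 0) return(NA_real_)
  hits <- vapply(truth_boxes, function(tb) {
    any(vapply(detected, function(d) iou(d, tb) >= thr, logical(1)))
  }, logical(1))
  mean(hits)
}
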