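#' Segmentation parameters for automatic labeling
#'
#' Bundles every tunable of the classical segmentation chain used both to
#' auto-generate PASCAL VOC training labels and as the default detector for
#' tracking: Gaussian smoothing, edge-preserving bilateral filtering,
#' contrast-limited adaptive histogram equalization (CLAHE), fixed-threshold
#' binarization, morphological clean-up, and a size gate on the resulting
#' connected components.
#'
#' @param gaussian_ksize Odd Gaussian kernel side, pixels. Default 5.
#' @param gaussian_sigma Gaussian standard deviation; by default derived from
#'   the kernel size via [gaussian_sigma_from_ksize()] (1.1 for ksize 5).
#' @param bilateral_sigma_color Range sigma of the bilateral filter, gray
#'   levels. Default 75.
#' @param bilateral_sigma_space Spatial sigma of the bilateral filter,
#'   pixels. Default 75.
#' @param bilateral_diameter Neighbourhood diameter of the bilateral filter,
#'   pixels. Default 40.
#' @param clahe_clip CLAHE contrast limit. Default 1.0.
#' @param clahe_grid CLAHE tile grid (columns, rows). Default `c(50, 50)`.
#'   For small frames the grid is reduced so each tile spans at least 8
#'   pixels per side (a numerical guard; the default is intended for
#'   full-resolution 1024 x 760 video).
#' @param binarize_threshold Gray level separating animal from floor after
#'   equalization. Default 100; with `invert_polarity = FALSE` pixels
#'   strictly below the threshold are foreground (dark animal on a light
#'   floor).
#' @param invert_polarity Set `TRUE` for light animals on a dark floor.
#' @param erode_iters,dilate_iters Iterations of binary erosion then dilation
#'   with a 5 x 5 rectangular structuring element. Defaults 3 and 4.
#' @param max_box Maximum accepted box side lengths `c(width, height)` in
#'   pixels; larger components are rejected as non-animal regions. Default
#'   `c(200, 200)`.
#' @param arena_roi Optional rectangle `c(xmin, ymin, xmax, ymax)`; boxes
#'   whose center falls outside it are discarded.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(gaussian_ksize = 5,
                       gaussian_sigma = gaussian_sigma_from_ksize(gaussian_ksize),
                       bilateral_sigma_color = 75,
                       bilateral_sigma_space = 75,
                       bilateral_diameter = 40,
                       clahe_clip = 1.0,
                       clahe_grid = c(50, 50),
                       binarize_threshold = 100,
                       invert_polarity = FALSE,
                       erode_iters = 3,
                       dilate_iters = 4,
                       max_box = c(200, 200),
                       arena_roi = NULL) {
  if (gaussian_ksize < 1 || gaussian_ksize %% 2 == 0)
    stop("gaussian_ksize must be a positive odd integer")
  if (binarize_threshold < 0 || binarize_threshold > 255)
    stop("binarize_threshold must lie in [0, 255]")
  if (erode_iters < 0 || dilate_iters < 0)
    stop("morphology iteration counts must be >= 0")
  if (any(max_box <= 0)) stop("max_box must be positive")
  structure(
    list(gaussian_ksize = gaussian_ksize, gaussian_sigma = gaussian_sigma,
         bilateral_sigma_color = bilateral_sigma_color,
         bilateral_sigma_space = bilateral_sigma_space,
         bilateral_diameter = bilateral_diameter,
         clahe_clip = clahe_clip, clahe_grid = rep(clahe_grid, length.out = 2),
         binarize_threshold = binarize_threshold,
         invert_polarity = invert_polarity,
         erode_iters = erode_iters, dilate_iters = dilate_iters,
         max_box = rep(max_box, length.out = 2), arena_roi = arena_roi),
    class = "seg_params"
  )
}

#' Gaussian sigma derived from kernel size
#'
#' The conventional rule tying the standard deviation of a Gaussian smoothing
#' kernel to its side length: `sigma = 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8`.
#' For the default 5 x 5 kernel this gives sigma = 1.1 pixels.
#'
#' @param ksize Odd positive kernel side, pixels.
#' @return Sigma in pixels.
#' @examples
#' gaussian_sigma_from_ksize(5) # 1.1
#' @export
gaussian_sigma_from_ksize <- function(ksize) {
  if (!is.numeric(ksize) || length(ksize) != 1 || ksize < 1 || ksize %% 2 == 0)
    stop("ksize must be a positive odd integer")
  0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
}

#' 2-D Gaussian smoothing kernel
#'
#' Builds the 1-D Gaussian `exp(-x^2 / (2 sigma^2))` on the integer offsets
#' `-(ksize-1)/2 .. (ksize-1)/2`, forms the 2-D kernel as its outer product
#' with itself, and normalizes the result to unit sum. The kernel is
#' symmetric under horizontal and vertical reflection and under transpose.
#'
#' @param ksize Odd positive kernel side.
#' @param sigma Standard deviation in pixels, > 0. Defaults to
#'   [gaussian_sigma_from_ksize()].
#' @return A `ksize` x `ksize` matrix whose entries sum to 1.
#' @export
gaussian_kernel <- function(ksize, sigma = gaussian_sigma_from_ksize(ksize)) {
  if (ksize < 1 || ksize %% 2 == 0) stop("ksize must be a positive odd integer")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  r <- (ksize - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian smoothing stage
#'
#' Convolves the frame with [gaussian_kernel()], replicating edge pixels at
#' the border. Color frames are processed per channel.
#'
#' @param img Frame (matrix or BGR array), 0..255 scale.
#' @param ksize,sigma Kernel parameters, see [gaussian_kernel()].
#' @return The smoothed frame, same shape.
#' @export
gaussian_smooth <- function(img, ksize = 5,
                            sigma = gaussian_sigma_from_ksize(ksize)) {
  check_frame(img)
  k <- gaussian_kernel(ksize, sigma)
  per_channel(img, function(ch) .conv2_replicate(ch, k))
}

#' Bilateral filtering stage
#'
#' Edge-preserving smoothing: each output pixel is a weighted mean over a
#' circular neighbourhood, with weights that decay both with spatial distance
#' (sigma_space) and with gray-value difference from the center pixel
#' (sigma_color), so noise is averaged away while animal/floor edges are
#' kept. Borders replicate edge pixels.
#'
#' @param img Frame, 0..255 scale.
#' @param diameter Neighbourhood diameter, pixels.
#' @param sigma_color Range sigma, gray levels.
#' @param sigma_space Spatial sigma, pixels.
#' @return The filtered frame, same shape.
#' @export
bilateral_smooth <- function(img, diameter = 40, sigma_color = 75,
                             sigma_space = 75) {
  check_frame(img)
  per_channel(img, function(ch)
    .bilateral_replicate(ch, as.integer(diameter), sigma_color, sigma_space))
}

per_channel <- function(img, f) {
  if (!is_color(img)) return(f(img))
  out <- img
  for (c in seq_len(dim(img)[3])) out[, , c] <- f(img[, , c])
  out
}

#' Smooth a frame (Gaussian then bilateral)
#'
#' The two-stage denoising front of the segmentation chain: Gaussian
#' convolution removes sensor noise, then the bilateral filter smooths
#' remaining small fluctuations while preserving the animal/floor edge.
#'
#' @param img Frame on the 0..255 scale.
#' @param params A [seg_params()] object.
#' @return The smoothed frame, same shape and intensity scale.
#' @export
smooth_image <- function(img, params = seg_params()) {
  img <- gaussian_smooth(img, params$gaussian_ksize, params$gaussian_sigma)
  bilateral_smooth(img, params$bilateral_diameter,
                   params$bilateral_sigma_color, params$bilateral_sigma_space)
}

# CLAHE via EBImage; EBImage wants [x, y] images with dims that are multiples
# of the tile grid, so pad by edge replication and crop back.
apply_clahe <- function(gray, clip, grid) {
  h <- img_height(gray); w <- img_width(gray)
  nx <- max(1L, min(as.integer(grid[1]), w %/% 8L))
  ny <- max(1L, min(as.integer(grid[2]), h %/% 8L))
  x <- t(gray) / 255
  dx <- dim(x)
  px <- (nx - dx[1] %% nx) %% nx
  py <- (ny - dx[2] %% ny) %% ny
  if (px > 0) x <- rbind(x, x[rep(dx[1], px), , drop = FALSE])
  if (py > 0) x <- cbind(x, x[, rep(ncol(x), py), drop = FALSE])
  eq <- EBImage::clahe(x, nx = nx, ny = ny, limit = clip)
  t(eq[seq_len(w), seq_len(h), drop = FALSE]) * 255
}

binary_morph <- function(mask, erode_iters, dilate_iters) {
  brush <- EBImage::makeBrush(5, shape = "box")
  m <- t(mask)
  for (i in seq_len(erode_iters)) m <- EBImage::erode(m, brush)
  for (i in seq_len(dilate_iters)) m <- EBImage::dilate(m, brush)
  t(m)
}

#' Detect animal blobs in a frame by classical segmentation
#'
#' Runs the full segmentation chain: smooth ([smooth_image()]) -> grayscale
#' -> CLAHE -> fixed-threshold binarization (foreground = gray below the
#' threshold for dark animals) -> binary erosion x3 then dilation x4 with a
#' 5 x 5 rectangle -> connected components -> axis-aligned bounding boxes ->
#' size gate (components wider or taller than `max_box` are rejected, as is
#' anything centered outside `arena_roi` when one is set). This doubles as
#' the default detector of [track_video()] and as the box source of
#' [autolabel_frames()].
#'
#' @param frame A single video frame, 0..255 scale.
#' @param params A [seg_params()] object.
#' @return A list of `bbox` objects with score 1.0.
#' @export
detect_blobs <- function(frame, params = seg_params()) {
  check_frame(frame)
  sm <- smooth_image(frame, params)
  gray <- to_gray(sm)
  eq <- apply_clahe(gray, params$clahe_clip, params$clahe_grid)
  fg <- if (params$invert_polarity) eq > params$binarize_threshold
        else eq < params$binarize_threshold
  fg <- binary_morph(fg, params$erode_iters, params$dilate_iters)
  lab <- t(EBImage::bwlabel(t(fg)))
  n <- max(lab)
  if (n == 0) return(list())
  h <- img_height(frame); w <- img_width(frame)
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    ymin <- min(idx[, 1]) - 1L; ymax <- max(idx[, 1])   # half-open, 0-based
    xmin <- min(idx[, 2]) - 1L; xmax <- max(idx[, 2])
    bw <- xmax - xmin; bh <- ymax - ymin
    if (bw > params$max_box[1] || bh > params$max_box[2]) next
    if (!is.null(params$arena_roi)) {
      cx <- (xmin + xmax) / 2; cy <- (ymin + ymax) / 2
      r <- params$arena_roi
      if (cx < r[1] || cy < r[2] || cx > r[3] || cy > r[4]) next
    }
    out[[length(out) + 1L]] <- bbox(xmin, ymin, xmax, ymax, score = 1.0)
  }
  out
}

#' Auto-generate PASCAL VOC labels for a frame sequence
#'
#' Runs [detect_blobs()] on every frame and writes one VOC XML annotation per
#' frame, ready for inspection or manual correction in LabelImg.
#'
#' @param frames A list of frames, or a function `frames(i)` returning frame
#'   `i` (see [track_video()]).
#' @param n_frames Number of frames when `frames` is a function.
#' @param out_dir Directory receiving `frame_000001.xml`, ...
#' @param params A [seg_params()] object.
#' @param folder Folder name recorded inside each annotation.
#' @return Invisibly, the vector of files written.
#' @export
autolabel_frames <- function(frames, n_frames = length(frames),
                             out_dir = ".", params = seg_params(),
                             folder = "frames") {
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(n_frames)
  for (i in seq_len(n_frames)) {
    fr <- get_frame(i)
    boxes <- detect_blobs(fr, params)
    fn <- sprintf("frame_%06d", i)
    ann <- voc_annotation(folder = folder, filename = paste0(fn, ".png"),
                          width = img_width(fr), height = img_height(fr),
                          depth = if (is_color(fr)) 3L else 1L,
                          objects = boxes)
    paths[i] <- file.path(out_dir, paste0(fn, ".xml"))
    write_voc(ann, paths[i])
  }
  invisible(paths)
}
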