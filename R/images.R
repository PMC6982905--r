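# Image conventions: a grayscale frame is a numeric matrix indexed [y, x]
# (nrow = height, ncol = width), intensities on the 8-bit 0..255 scale. A
# color frame is an array dim c(height, width, 3) in B, G, R channel order.

img_height <- function(img) dim(img)[1]
img_width  <- function(img) dim(img)[2]

is_color <- function(img) length(dim(img)) == 3L

check_frame <- function(img) {
  if (is.null(dim(img)) || length(dim(img)) < 2 || any(dim(img)[1:2] < 1) ||
      length(img) == 0)
    stop("empty or malformed frame")
  invisible(img)
}

#' Convert a color frame to grayscale
#'
#' Uses the standard luma weights (B 0.114, G 0.587, R 0.299). Grayscale
#' input is returned unchanged.
#'
#' @param img Matrix (grayscale) or height x width x 3 array in BGR order,
#'   0..255.
#' @return A grayscale matrix on the same intensity scale.
#' @export
to_gray <- function(img) {
  check_frame(img)
  if (!is_color(img)) return(img)
  0.114 * img[, , 1] + 0.587 * img[, , 2] + 0.299 * img[, , 3]
}

# Sample a pixel at 0-based coordinates (x, y), rounding to the nearest pixel
# and clipping to the image. Optionally average a (2r+1)^2 patch.
sample_gray <- function(gray, x, y, patch_radius = 0) {
  h <- img_height(gray); w <- img_width(gray)
  xi <- min(max(round(x), 0), w - 1)
  yi <- min(max(round(y), 0), h - 1)
  if (patch_radius <= 0) return(gray[yi + 1, xi + 1])
  xs <- max(0, xi - patch_radius):min(w - 1, xi + patch_radius)
  ys <- max(0, yi - patch_radius):min(h - 1, yi + patch_radius)
  mean(gray[ys + 1, xs + 1])
}
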