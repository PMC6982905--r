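test_that("kernel-size rule gives the documented sigmas", {
  expect_equal(gaussian_sigma_from_ksize(5), 1.1)
  expect_equal(gaussian_sigma_from_ksize(3), 0.8)
  expect_equal(gaussian_sigma_from_ksize(1), 0.5)
  expect_error(gaussian_sigma_from_ksize(4), "odd")
  expect_error(gaussian_sigma_from_ksize(-3), "odd|positive")
  expect_equal(seg_params()$gaussian_sigma, 1.1)
})

test_that("gaussian kernel is a normalized symmetric outer product", {
  expect_equal(gaussian_kernel(1), matrix(1, 1, 1))
  # flat limit: a huge sigma approaches the uniform kernel
  k3 <- gaussian_kernel(3, sigma = 1e6)
  expect_equal(k3, matrix(1 / 9, 3, 3), tolerance = 1e-10)
  for (ks in c(3, 5, 7)) for (s in c(0.6, 1.1, 3)) {
    k <- gaussian_kernel(ks, s)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, t(k))
    expect_equal(k, k[ks:1, ])
    expect_equal(which.max(k), (ks^2 + 1) %/% 2)  # center entry is the max
  }
  expect_error(gaussian_kernel(5, 0), "sigma")
})

test_that("gaussian stage reproduces the kernel as its impulse response", {
  img <- matrix(0, 11, 11)
  img[6, 6] <- 1
  sm <- gaussian_smooth(img, 5, 1.1)
  expect_equal(sm[4:8, 4:8], gaussian_kernel(5, 1.1), tolerance = 1e-12)
  # constants are preserved by both stages
  flat <- matrix(137, 40, 50)
  expect_equal(smooth_image(flat), flat, tolerance = 1e-9)
})

test_that("smoothing reduces the variance of salt-and-pepper noise", {
  set.seed(42)
  img <- matrix(128, 60, 80)
  at <- sample(length(img), 48)
  img[at] <- sample(c(0, 255), 48, replace = TRUE)
  out <- smooth_image(img)
  expect_lt(stats::var(as.numeric(out)), stats::var(as.numeric(img)))
})

test_that("blob detection finds dark ellipses and gates out large regions", {
  expect_equal(detect_blobs(matrix(180, 300, 400)), list())
  expect_error(detect_blobs(matrix(numeric(0), 0, 0)), "empty")

  one <- ellipse_frame(400, 300, cbind(200, 150))
  found <- detect_blobs(one)
  expect_length(found, 1)
  truth <- bbox(170, 135, 230, 165)
  expect_gte(iou(found[[1]], truth), 0.8)
  expect_equal(found[[1]]$score, 1.0)

  # three well-separated animals plus one 300x300 dark region: the region is
  # wider than the 200x200 gate and must be rejected
  multi <- ellipse_frame(700, 620, rbind(c(120, 120), c(520, 140), c(150, 420)))
  multi[300:599, 380:679] <- 60
  found <- detect_blobs(multi)
  expect_length(found, 3)
  for (b in found) {
    expect_lte(b$xmax - b$xmin, 200)
    expect_lte(b$ymax - b$ymin, 200)
  }
})

test_that("box coordinates stay inside the frame and survive mild noise", {
  set.seed(77)
  fr <- ellipse_frame(400, 300, rbind(c(60, 60), c(330, 240)))
  base <- detect_blobs(fr)
  expect_length(base, 2)
  for (rep in 1:3) {
    noisy <- fr
    at <- sample(length(fr), round(0.01 * length(fr)))
    noisy[at] <- sample(c(0, 255), length(at), replace = TRUE)
    found <- detect_blobs(noisy)
    expect_length(found, length(base))
    for (b in found) {
      expect_gte(b$xmin, 0); expect_gte(b$ymin, 0)
      expect_lte(b$xmax, 400); expect_lte(b$ymax, 300)
    }
  }
})

test_that("arena_roi discards detections centered outside it", {
  fr <- ellipse_frame(400, 300, rbind(c(60, 60), c(330, 240)))
  p <- seg_params(arena_roi = c(0, 0, 200, 300))
  found <- detect_blobs(fr, p)
  expect_length(found, 1)
  expect_lt(box_center(found[[1]])["x"], 200)
})

test_that("segmentation recall on rendered scenes is high", {
  sc <- arena_scene(width = 480, height = 360, n_animals = 2, n_frames = 10,
                    noise_sigma = 0, sp_density = 0, seed = 15)
  hits <- 0; total <- 0
  for (i in seq_len(10)) {
    found <- detect_blobs(render_frame(sc, i))
    tr <- sc$truth[sc$truth$frame == i, ]
    tb <- lapply(seq_len(nrow(tr)), function(k)
      true_bbox(tr$x[k], tr$y[k], tr$vx[k], tr$vy[k]))
    r <- recall_at_iou(found, tb)
    hits <- hits + r * length(tb); total <- total + length(tb)
  }
  expect_gte(hits / total, 0.95)
})
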