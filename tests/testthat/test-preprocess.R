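test_that("rescaling hits the target in the maximal dimension", {
  img <- array(runif(200 * 150 * 3), c(200, 150, 3))
  r <- rescale_max_dim(img, 100)
  expect_equal(dim(r), c(100L, 75L, 3L))     # exact halving
  img2 <- array(runif(100 * 40 * 3), c(100, 40, 3))
  expect_identical(rescale_max_dim(img2, 100), img2)  # already at target
  # upscaling is applied too, and the aspect ratio is kept within a pixel
  up <- rescale_max_dim(img2, 150)
  expect_equal(dim(up)[1], 150L)
  expect_lte(abs(dim(up)[2] - 40 * 150 / 100), 1)
  expect_error(rescale_max_dim(array(0.5, c(1, 1, 3)), 100), "invalid")
})

test_that("bilinear rescaling preserves a linear gradient", {
  side <- 99
  g <- matrix(rep(seq(0, 1, length.out = side), side), side, side)
  img <- array(rep(g, 3), c(side, side, 3))
  r <- rescale_max_dim(img, 300)
  expect_equal(dim(r)[1:2], c(300L, 300L))
  # against the independent analytic resampling oracle: a linear ramp must
  # stay a linear ramp (up to edge handling), constant across the other axis
  mid <- r[, 150, 1]
  fit <- lm(mid ~ seq_along(mid))
  expect_lt(max(abs(residuals(fit))), 0.01)
  # the ramp runs down the rows, so each row stays constant
  expect_lt(max(abs(r[30, , 1] - r[30, 1, 1])), 1e-6)
  expect_lt(max(abs(r[270, , 1] - r[270, 1, 1])), 1e-6)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("crop/pad squares up around the mask with zero padding", {
  set.seed(31)
  img <- array(runif(200 * 200 * 3, min = 0.2), c(200, 200, 3))
  mask <- matrix(FALSE, 200, 200)
  mask[51:150, 76:125] <- TRUE   # 100 x 50 centred box
  out <- crop_pad_square(img, mask, side = 100)
  expect_equal(dim(out), c(100L, 100L, 3L))
  # brute-force geometry: 25 blank columns each side, no resampling needed
  expect_equal(max(abs(out[, 1:25, ])), 0)
  expect_equal(max(abs(out[, 76:100, ])), 0)
  expect_equal(out[, 26:75, ], img[51:150, 76:125, ], tolerance = 1e-12)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[100, 100, 3], 0)
})

test_that("crop/pad handles full-image masks and rejects empty ones", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- crop_pad_square(img, matrix(TRUE, 64, 64), side = 64)
  expect_equal(out, img, tolerance = 1e-12)   # square, full mask: unchanged
  expect_error(crop_pad_square(img, matrix(FALSE, 64, 64), side = 64),
               "segmentation failure")
})

test_that("both squaring orders give a canonical frame in [0, 1]", {
  sim <- simulate_lesion_image(seed = 41, class = "benign", side = 160,
                               axes = c(50, 30))
  for (order_flag in c(TRUE, FALSE)) {
    out <- crop_pad_square(sim$image, sim$mask, side = 128,
                           pad_then_resize = order_flag)
    expect_equal(dim(out), c(128L, 128L, 3L))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("the full preprocessing chain lands on side x side x 3 in [0, 1]", {
  sim <- simulate_lesion_image(seed = 32, class = "excise", side = 300,
                               axes = c(80, 60))
  img <- sim$image[1:260, , , drop = FALSE]   # non-square input
  pp <- preprocess_image(img, target = 320, side = 128, seg_maxdim = 128)
  expect_s3_class(pp, "preprocessed_lesion")
  expect_equal(dim(pp$frame), c(128L, 128L, 3L))
  expect_true(all(pp$frame >= 0 & pp$frame <= 1))
  expect_true(any(pp$mask))
  expect_length(pp$bbox, 4)
})

test_that("images round-trip through PNG", {
  img <- array(round(runif(32 * 48 * 3) * 255) / 255, c(32, 48, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_lesion_png(img, path)
  back <- read_lesion_image(path)
  expect_equal(back, img, tolerance = 1e-7)
  m <- matrix(c(TRUE, FALSE), 32, 48)
  pathm <- withr::local_tempfile(fileext = ".png")
  write_lesion_png(m, pathm)
  backm <- read_lesion_image(pathm)
  expect_equal(backm[, , 1] > 0.5, m)
})
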