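# Grad-CAM heatmaps and overlays.

# Hand-built two-layer toy model: a fixed 1x1 convolution producing two
# channels, global average pooling, and a linear head whose first-class
# weight reads only channel 1. The class-1 logit is then a positive multiple
# of the mean of channel 1, so its Grad-CAM heatmap must be proportional to
# that channel's rectified activation.
toy_model <- function(beta = 3) {
  conv <- msfnet:::conv_make(3, 2, k = 1, pad = 0)
  conv$params$w <- array(0, c(2, 3, 1, 1))
  conv$params$w[1, 1, 1, 1] <- 1        # channel 1 <- red
  conv$params$w[2, 2, 1, 1] <- 1        # channel 2 <- green
  fc <- msfnet:::dense_make(2, 2)
  fc$params$w <- matrix(c(beta, 0, 0, 1), 2, byrow = TRUE)
  fc$params$b <- c(0, 0)
  structure(list(config = list(num_classes = 2L, resolution = 16L),
                 layers = list(feat = conv, gap = msfnet:::gap_make(),
                               fc = fc),
                 classes = c("one", "two"),
                 norm_stats = list(mean = rep(0.5, 3), sd = rep(0.5, 3))),
            class = "msf_model")
}

random_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

test_that("heatmaps are normalized to [0, 1] at the input image's size", {
  m <- toy_model()
  img <- random_image(20, 14)
  hm <- grad_cam(m, img, target_class = 1, layer = "feat")
  expect_identical(dim(hm$values), c(20L, 14L))
  expect_gte(min(hm$values), 0)
  expect_lte(max(hm$values), 1)
  expect_equal(max(hm$values), 1)
  expect_false(hm$constant)
})

test_that("on the analytic toy model the heatmap is the rectified designated
           channel, correlation >= 0.99", {
  m <- toy_model(beta = 5)
  img <- random_image(16, 16, seed = 3)
  hm <- grad_cam(m, img, target_class = 1, layer = "feat")

  # expected: channel-1 activation = standardized red channel, rectified,
  # then min-max normalized (no upsampling: activation is input-sized)
  red <- (img[, , 1] / 255 - 0.5) / 0.5
  expected <- pmax(red, 0)
  expected <- (expected - min(expected)) / (max(expected) - min(expected))
  expect_gt(cor(as.vector(hm$values), as.vector(expected)), 0.99)
  expect_equal(hm$values, expected, tolerance = 1e-6)
})

test_that("grad_cam is deterministic and validates its arguments", {
  m <- toy_model()
  img <- random_image(16, 16, seed = 4)
  h1 <- grad_cam(m, img, target_class = 2, layer = "feat")
  h2 <- grad_cam(m, img, target_class = 2, layer = "feat")
  expect_identical(h1$values, h2$values)
  expect_error(grad_cam(m, img, target_class = 1, layer = "nope"),
               "no layer")
  expect_error(grad_cam(m, img, target_class = 1, layer = "gap"),
               "spatial")
  expect_error(grad_cam(m, img, target_class = 9, layer = "feat"), "range")
})

test_that("a constant raw map normalizes to zeros with the constant flag", {
  m <- toy_model()
  m$layers$fc$params$w <- matrix(0, 2, 2)    # zero head: zero gradients
  img <- random_image(16, 16, seed = 5)
  hm <- grad_cam(m, img, target_class = 1, layer = "feat")
  expect_true(hm$constant)
  expect_true(all(hm$values == 0))
})

test_that("grad_cam works on the full classifier at its fusion module", {
  model <- build_model(tiny_model_config(resolution = 32), seed = 2)
  model$classes <- paste0("c", 1:5)
  img <- random_image(32, 32, seed = 6)
  hm <- grad_cam(model, img, target_class = 3)
  expect_identical(hm$layer, "msfm")
  expect_identical(dim(hm$values), c(32L, 32L))
  expect_true(all(hm$values >= 0 & hm$values <= 1))
})

test_that("overlay blends by opacity: 0 returns the image, 1 the pure
           colormap, 0.5 the hand-computed mixture", {
  img <- flat_image(4, 4, c(100, 150, 200))
  hm <- matrix(0.3, 4, 4)
  expect_equal(overlay(img, hm, opacity = 0), img, ignore_attr = TRUE)

  pure <- overlay(img, hm, opacity = 1)
  cmap_rgb <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
  idx <- floor(0.3 * 255) + 1
  for (ch in 1:3) expect_true(all(pure[, , ch] == cmap_rgb[ch, idx]))

  half <- overlay(img, hm, opacity = 0.5)
  for (ch in 1:3) {
    expect_true(all(half[, , ch] ==
                      round(0.5 * c(100, 150, 200)[ch] +
                              0.5 * cmap_rgb[ch, idx])))
  }
  expect_error(overlay(img, matrix(0.5, 2, 2)), "disagree")
  expect_error(overlay(img, hm, opacity = 2), "opacity")
})

test_that("the comparison grid concatenates panels side by side", {
  img <- flat_image(8, 6, c(10, 20, 30))
  ov <- flat_image(8, 6, c(200, 100, 0))
  out <- file.path(tempdir(), "grid.png")
  save_comparison_grid(img, list(model = ov), out)
  grid <- read_image(out)
  expect_identical(dim(grid)[1], 8L)
  expect_gte(dim(grid)[2], 12L)
})
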