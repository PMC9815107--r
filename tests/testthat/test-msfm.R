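# Dilated-convolution arithmetic and the multi-scale fusion module.

test_that("expanded kernel side follows k + (k-1)(r-1)", {
  expect_identical(dilated_kernel_size(3, 2), 5)   # the 5x5-equivalent case
  expect_identical(dilated_kernel_size(3, 1), 3)
  expect_identical(dilated_kernel_size(5, 3), 13)
  expect_error(dilated_kernel_size(0, 1), "positive")
  expect_error(dilated_kernel_size(3, 0), "positive")
})

test_that("gradient-footprint oracle agrees with the expanded-kernel formula", {
  # a dilated conv applied to a delta image marks exactly the tap positions;
  # the bounding-box side of the nonzero support is the expanded kernel side
  for (spec in list(c(3, 1), c(3, 2), c(3, 4), c(5, 3))) {
    k <- spec[1]; r <- spec[2]
    side <- 2L * dilated_kernel_size(k, r) + 5L
    delta <- array(0, c(1, side, side))
    mid <- (side + 1L) %/% 2L
    delta[1, mid, mid] <- 1
    w <- array(1, c(1, 1, k, k))
    out <- brute_conv2d(delta, w, pad = (k - 1) / 2 * r, dil = r)
    expect_identical(footprint_side(out[1, , ]),
                     as.integer(dilated_kernel_size(k, r)))
  }
})

test_that("dilated branches preserve spatial extent, keep 9 weights per
           channel pair, and reproduce the footprint", {
  set.seed(3)
  f <- array(rnorm(2 * 10 * 10), c(2, 10, 10))
  for (r in c(1, 2, 4)) {
    out <- dilated_branch(f, out_channels = 3, r = r, seed = r)
    expect_identical(dim(out), c(3L, 10L, 10L))
    # single-in/single-out branch: exactly 9 trainable weights whatever r
    p <- msfnet:::conv_make(1, 1, k = 3, pad = r, dilation = r)
    expect_identical(msfnet:::param_count(msfnet:::layer_params(p)), 9L)
  }
  expect_error(dilated_branch(f, 3, r = 0), ">= 1")
})

test_that("rate-1 branch is an ordinary same-padded 3x3 convolution", {
  set.seed(4)
  f <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  p <- msfnet:::conv_make(2, 2, k = 3, pad = 1, dilation = 1)
  got <- dilated_branch(f, 2, r = 1, params = p)
  expect_equal(got, brute_conv2d(f, p$params$w, pad = 1), tolerance = 1e-12)
})

test_that("a rate-4 branch on a delta image has a 9x9 nonzero support box", {
  delta <- array(0, c(1, 25, 25))
  delta[1, 13, 13] <- 1
  p <- msfnet:::conv_make(1, 1, k = 3, pad = 4, dilation = 4)
  p$params$w <- array(1, c(1, 1, 3, 3))
  out <- dilated_branch(delta, 1, r = 4, params = p)
  expect_identical(footprint_side(out[1, , ]), 9L)   # 3 + 2*(4-1)*... = 9
})

test_that("msfm output shape is (c_out, H, W) and zero weights give zeros", {
  f <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  p <- msfm_params(4, c_branch = 2, c_out = 6, seed = 1)
  out <- msfm_forward(f, params = p)
  expect_identical(dim(out), c(6L, 8L, 8L))

  pz <- msfm_params(4, c_branch = 2, c_out = 6, norm_act = FALSE, seed = 1)
  pz <- msfnet:::layer_set_params(
    pz, msfnet:::param_map(function(a) a * 0, msfnet:::layer_params(pz)))
  expect_equal(msfm_forward(f, params = pz), array(0, c(6, 8, 8)))
})

test_that("msfm equals the independently scripted branch/concat/reduce
           composition on a 4x8x8 instance", {
  set.seed(17)
  f <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  p <- msfm_params(4, c_branch = 2, c_out = 4, norm_act = FALSE,
                   reduction_ratio = 2, spatial_kernel = 3, seed = 18)
  got <- msfm_forward(f, params = p)

  g <- cbam(f, params = p$children$cbam)
  branches <- lapply(c(1, 2, 4), function(r) {
    brute_conv2d(g, p$children[[paste0("branch", r)]]$params$w,
                 pad = r, dil = r)
  })
  concat <- array(0, c(6, 8, 8))
  concat[1:2, , ] <- branches[[1]]
  concat[3:4, , ] <- branches[[2]]
  concat[5:6, , ] <- branches[[3]]
  red <- brute_conv2d(concat, p$children$reduce$params$w, pad = 0)
  expect_equal(got, red, tolerance = 1e-10)
})

test_that("msfm is deterministic given parameters and input", {
  f <- array(rnorm(3 * 6 * 6), c(3, 6, 6))
  p <- msfm_params(3, seed = 5)
  expect_identical(msfm_forward(f, params = p), msfm_forward(f, params = p))
})

test_that("msfm backward matches numeric gradients through all children", {
  set.seed(41)
  ly <- msfnet:::msfm_make(3, c_branch = 2, c_out = 3, reduction_ratio = 2,
                           spatial_kernel = 3)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  fw <- msfnet:::layer_forward(ly, x, training = TRUE)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- msfnet:::layer_backward(ly, fw$cache, dy)
  ng <- num_grad(function(xx)
    sum(msfnet:::layer_forward(ly, xx, TRUE)$y * dy), x, eps = 1e-5)
  expect_equal(bk$dx, ng, tolerance = 1e-5)
  ngw <- num_grad(function(ww) {
    l2 <- ly
    l2$children$branch4$params$w <- ww
    sum(msfnet:::layer_forward(l2, x, TRUE)$y * dy)
  }, ly$children$branch4$params$w)
  expect_equal(bk$grads$children$branch4$w, ngw, tolerance = 1e-5)
})
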