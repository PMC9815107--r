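# Channel attention, spatial attention and their CBAM composition.

test_that("channel attention gives 0.5 for zero parameters and matches the
           hand-traced identity-MLP case", {
  # zero MLP: sigmoid(0) for every channel, whatever the input
  f <- array(3, c(4, 2, 2))
  w <- channel_attention(f, params = zero_cbam_params(4))
  expect_equal(w, rep(0.5, 4))

  # C = 2, H = W = 1, identity MLP (reduction 1): shared MLP applied to the
  # max- and avg-pooled descriptors (both equal [1, 3]) sums to [2, 6]
  p <- cbam_params(2, reduction_ratio = 1, seed = 1)
  p$params$mlp_w1 <- diag(2)
  p$params$mlp_w2 <- diag(2)
  f <- array(c(1, 3), c(2, 1, 1))
  expect_equal(channel_attention(f, params = p), plogis(c(2, 6)),
               tolerance = 1e-12)
})

test_that("channel attention output is length C with entries in (0,1)", {
  for (cc in c(1, 3, 17)) {
    f <- array(rnorm(cc * 4 * 5), c(cc, 4, 5))
    w <- channel_attention(f, seed = cc)
    expect_length(w, cc)
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("channel attention rejects invalid input", {
  f <- array(1, c(2, 2, 2))
  f[1] <- NA
  expect_error(channel_attention(f), "non-finite")
  expect_error(channel_attention(array(1, c(2, 2, 2)), reduction_ratio = 0),
               "positive")
})

test_that("channel attention is equivariant under consistent channel
           permutation", {
  set.seed(5)
  f <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  p <- cbam_params(3, reduction_ratio = 1, seed = 9)
  perm <- c(3, 1, 2)
  p2 <- p
  p2$params$mlp_w1 <- p$params$mlp_w1[perm, perm]
  p2$params$mlp_w2 <- p$params$mlp_w2[perm, perm]
  w1 <- channel_attention(f, params = p)
  w2 <- channel_attention(f[perm, , , drop = FALSE], params = p2)
  expect_equal(w2, w1[perm], tolerance = 1e-12)
})

test_that("spatial attention: zero conv gives a uniform 0.5 map and constant
           inputs give spatially uniform maps", {
  f <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  m <- spatial_attention(f, kernel_size = 3,
                         params = zero_cbam_params(3, spatial_kernel = 3))
  expect_identical(dim(m), c(4L, 6L))
  expect_true(all(m == 0.5))

  # spatially constant input -> channel max/mean maps constant -> uniform gate
  fc <- array(rep(c(0.3, -1, 2), each = 1), c(3, 1, 1))[, rep(1, 5),
                                                        rep(1, 5), drop = FALSE]
  dim(fc) <- c(3, 5, 5)
  m2 <- spatial_attention(fc, kernel_size = 3, seed = 4)
  expect_lt(diff(range(m2)), 1e-12)
})

test_that("spatial attention matches a brute-force convolution oracle", {
  f <- array(0, c(1, 3, 3))
  f[1, , ] <- diag(3) * 2 + 0.5
  k <- array(rnorm(9 * 2), c(1, 2, 3, 3))
  p <- cbam_params(1, spatial_kernel = 3, seed = 2)
  p$params$sp_w <- k
  got <- spatial_attention(f, kernel_size = 3, params = p)

  # oracle: channel max = channel mean = the single channel; concat; direct
  # 2-D convolution over the edge-replicated map; sigmoid
  pooled <- array(0, c(2, 3, 3))
  pooled[1, , ] <- f[1, , ]
  pooled[2, , ] <- f[1, , ]
  z <- brute_conv2d(brute_replicate_pad(pooled, 1), k, pad = 0)
  expect_equal(got, plogis(z[1, , ]), tolerance = 1e-12)
})

test_that("cbam: zero input stays zero, zero parameters scale by 0.25, and
           shape is always preserved", {
  z <- array(0, c(3, 4, 4))
  expect_identical(cbam(z, seed = 1), z)

  f <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  expect_equal(cbam(f, params = zero_cbam_params(3)), 0.25 * f,
               tolerance = 1e-12)

  for (d in list(c(1, 1, 1), c(2, 3, 5), c(8, 7, 7))) {
    fi <- array(rnorm(prod(d)), d)
    expect_identical(dim(cbam(fi, seed = 3)), as.integer(d))
  }
})

test_that("cbam gating never amplifies: |cbam(f)| <= |f| elementwise", {
  set.seed(11)
  for (i in 1:5) {
    f <- array(rnorm(4 * 6 * 6, sd = 2), c(4, 6, 6))
    g <- cbam(f, seed = i)
    expect_true(all(abs(g) <= abs(f) + 1e-12))
  }
})

test_that("cbam equals an independently scripted elementwise gate product on
           a 2x4x4 instance", {
  set.seed(21)
  f <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  p <- cbam_params(2, reduction_ratio = 1, spatial_kernel = 3, seed = 22)
  got <- cbam(f, params = p)

  # --- independent script: channel gate ---
  avg <- apply(f, 1, mean)
  mx <- apply(f, 1, max)
  mlp <- function(v) {
    h <- pmax(p$params$mlp_w1 %*% v, 0)
    as.vector(p$params$mlp_w2 %*% h)
  }
  s <- plogis(mlp(avg) + mlp(mx))
  f1 <- f
  for (ci in 1:2) f1[ci, , ] <- f[ci, , ] * s[ci]
  # --- spatial gate ---
  pooled <- array(0, c(2, 4, 4))
  pooled[1, , ] <- apply(f1, c(2, 3), max)
  pooled[2, , ] <- apply(f1, c(2, 3), mean)
  m <- plogis(brute_conv2d(brute_replicate_pad(pooled, 1),
                           p$params$sp_w, pad = 0)[1, , ])
  expected <- f1
  for (ci in 1:2) expected[ci, , ] <- f1[ci, , ] * m
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("cbam backward matches numeric gradients", {
  set.seed(31)
  ly <- msfnet:::cbam_make(3, reduction_ratio = 2, spatial_kernel = 3)
  x <- array(rnorm(2 * 3 * 5 * 5), c(2, 3, 5, 5))
  fw <- msfnet:::layer_forward(ly, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- msfnet:::layer_backward(ly, fw$cache, dy)
  ng <- num_grad(function(xx) sum(msfnet:::layer_forward(ly, xx)$y * dy), x)
  expect_equal(bk$dx, ng, tolerance = 1e-6)
  for (pn in names(ly$params)) {
    ngp <- num_grad(function(pp) {
      l2 <- ly
      l2$params[[pn]] <- pp
      sum(msfnet:::layer_forward(l2, x)$y * dy)
    }, ly$params[[pn]])
    expect_equal(bk$grads[[pn]], ngp, tolerance = 1e-6)
  }
})
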