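# Convolutional block attention: channel gating from globally pooled
# descriptors through a shared two-layer MLP, then spatial gating from
# channel-wise max/mean maps through a single convolution. Both gates are
# sigmoid-squashed, so every weight lies strictly in (0, 1), and the module
# multiplies rather than replaces the incoming features.

cbam_hidden_width <- function(c_ch, reduction_ratio) {
  max(1L, c_ch %/% as.integer(reduction_ratio))
}

#' Create parameters for a CBAM block
#'
#' Allocates the shared channel-MLP weights and the spatial-attention
#' convolution kernel for a feature map with `c_ch` channels. The MLP is a
#' two-layer bottleneck (`c_ch -> max(1, floor(c_ch / reduction_ratio)) ->
#' c_ch`) with a ReLU in between and no biases; it is applied to both the
#' max-pooled and the average-pooled channel descriptor (shared weights).
#'
#' @param c_ch Number of channels of the feature map to be gated.
#' @param reduction_ratio Bottleneck reduction ratio of the channel MLP
#'   (default 16, the usual squeeze-excitation convention). The hidden width
#'   floors at 1, so no divisibility is required.
#' @param spatial_kernel Odd kernel size of the spatial-attention convolution
#'   (default 7).
#' @param seed Optional integer; when given, initialization is deterministic.
#' @return A CBAM layer object usable with [cbam()], [channel_attention()]
#'   and [spatial_attention()].
#' @export
cbam_params <- function(c_ch, reduction_ratio = 16L, spatial_kernel = 7L,
                        seed = NULL) {
  if (reduction_ratio < 1L) {
    stop("reduction_ratio must be a positive integer", call. = FALSE)
  }
  if (spatial_kernel %% 2L != 1L || spatial_kernel < 1L) {
    stop("spatial_kernel must be an odd positive integer", call. = FALSE)
  }
  make <- function() cbam_make(c_ch, reduction_ratio, spatial_kernel)
  if (is.null(seed)) make() else with_seed(seed, make())
}

cbam_make <- function(c_ch, reduction_ratio = 16L, spatial_kernel = 7L) {
  hid <- cbam_hidden_width(c_ch, reduction_ratio)
  structure(list(kind = "cbam",
                 params = list(
                   mlp_w1 = he_init(c(hid, c_ch), fan_in = c_ch),
                   mlp_w2 = he_init(c(c_ch, hid), fan_in = hid),
                   sp_w = he_init(c(1L, 2L, spatial_kernel, spatial_kernel),
                                  fan_in = 2L * spatial_kernel^2)),
                 buffers = list(),
                 cfg = list(c_ch = as.integer(c_ch),
                            reduction = as.integer(reduction_ratio),
                            kernel = as.integer(spatial_kernel))),
            class = "msf_layer")
}

# Channel-attention sub-forward on a batch; returns the (N, C) gate plus the
# quantities backward needs.
channel_att_fwd <- function(layer, x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  avg <- rowMeans(xm)
  mx <- row_max_idx(xm)
  avg_nc <- matrix(avg, d[1], d[2])
  max_nc <- matrix(mx$max, d[1], d[2])
  w1 <- layer$params$mlp_w1
  w2 <- layer$params$mlp_w2
  pre_a <- avg_nc %*% t(w1)
  pre_m <- max_nc %*% t(w1)
  h_a <- relu(pre_a)
  h_m <- relu(pre_m)
  z <- (h_a + h_m) %*% t(w2)
  s <- sigmoid(z)
  list(s = s, avg_nc = avg_nc, max_nc = max_nc, max_idx = mx$idx,
       pre_a = pre_a, pre_m = pre_m, h_a = h_a, h_m = h_m)
}

# Spatial-attention sub-forward; returns the (N, 1, H, W) gate and cache.
# The reducing convolution pads by edge replication (not zeros) so that a
# spatially constant map yields a spatially uniform gate, borders included.
spatial_att_fwd <- function(layer, x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 3L, 4L, 2L))
  dim(xp) <- c(d[1] * d[3] * d[4], d[2])
  cmean <- rowMeans(xp)
  cmx <- row_max_idx(xp)
  pooled <- array(0, c(d[1], 2L, d[3], d[4]))
  pooled[, 1L, , ] <- array(cmx$max, c(d[1], d[3], d[4]))
  pooled[, 2L, , ] <- array(cmean, c(d[1], d[3], d[4]))
  k <- layer$cfg$kernel
  p <- (k - 1L) %/% 2L
  padded <- replicate_pad(pooled, p)
  z <- conv2d_fwd_cpp(padded, layer$params$sp_w, numeric(0), 1L, 0L, 1L)
  m <- sigmoid(z)
  list(m = m, padded = padded, pad = p, cmax_idx = cmx$idx)
}

# Broadcast an (N,1,H,W) spatial gate over C channels.
expand_spatial <- function(m, c_ch) {
  d <- dim(m)
  out <- array(0, c(d[1], c_ch, d[3], d[4]))
  for (ci in seq_len(c_ch)) out[, ci, , ] <- m[, 1L, , ]
  out
}

cbam_forward <- function(layer, x) {
  d <- dim(x)
  ca <- channel_att_fwd(layer, x)
  f1 <- scale_nc(x, ca$s)
  sa <- spatial_att_fwd(layer, f1)
  mfull <- expand_spatial(sa$m, d[2])
  y <- f1 * mfull
  list(y = y,
       cache = list(x = x, ca = ca, f1 = f1, sa = sa, mfull = mfull, dims = d))
}

cbam_backward <- function(layer, cache, dy) {
  d <- cache$dims
  n <- d[1]; c_ch <- d[2]; h <- d[3]; w <- d[4]
  f1 <- cache$f1
  m <- cache$sa$m

  # ---- through the spatial gate: y = f1 * m (broadcast over channels)
  df1 <- dy * cache$mfull
  dm_full <- dy * f1
  dmp <- aperm(dm_full, c(1L, 3L, 4L, 2L))        # (N,H,W,C)
  dim(dmp) <- c(n * h * w, c_ch)
  dm <- array(rowSums(dmp), c(n, 1L, h, w))

  dz_sp <- dm * m * (1 - m)
  gs <- conv2d_bwd_cpp(cache$sa$padded, layer$params$sp_w, dz_sp,
                       1L, 0L, 1L, FALSE)
  d_pooled <- replicate_pad_backward(gs$dx, cache$sa$pad, h, w)  # (N,2,H,W)

  # route the channel-max/mean pooling gradients back into f1
  d_cmax <- as.vector(d_pooled[, 1L, , ])          # ordered (n,h,w)
  d_cmean <- as.vector(d_pooled[, 2L, , ])
  df1p <- aperm(df1, c(1L, 3L, 4L, 2L))
  dim(df1p) <- c(n * h * w, c_ch)
  df1p <- df1p + d_cmean / c_ch
  idx <- cbind(seq_len(n * h * w), cache$sa$cmax_idx)
  df1p[idx] <- df1p[idx] + d_cmax
  df1 <- aperm(array(df1p, c(n, h, w, c_ch)), c(1L, 4L, 2L, 3L))

  # ---- through the channel gate: f1 = x * s (broadcast over space)
  ca <- cache$ca
  dx <- scale_nc(df1, ca$s)
  ds <- sum_spatial(df1 * cache$x)                 # (N,C)
  dz <- ds * ca$s * (1 - ca$s)

  w1 <- layer$params$mlp_w1
  w2 <- layer$params$mlp_w2
  dw2 <- t(dz) %*% (ca$h_a + ca$h_m)
  dh_a <- (dz %*% w2) * (ca$pre_a > 0)
  dh_m <- (dz %*% w2) * (ca$pre_m > 0)
  dw1 <- t(dh_a) %*% ca$avg_nc + t(dh_m) %*% ca$max_nc
  davg <- dh_a %*% w1
  dmx <- dh_m %*% w1

  # distribute the avg-pool gradient; route the max-pool gradient
  dx <- dx + as.vector(davg) / (h * w)
  dxm <- dx
  dim(dxm) <- c(n * c_ch, h * w)
  idx2 <- cbind(seq_len(n * c_ch), ca$max_idx)
  dxm[idx2] <- dxm[idx2] + as.vector(dmx)
  dx <- array(dxm, d)

  list(dx = dx, grads = list(mlp_w1 = dw1, mlp_w2 = dw2, sp_w = gs$dw))
}

# ---- user-facing single-map operations ----------------------------------

#' Channel attention weights of a feature map
#'
#' Computes the per-channel gate of the channel attention mechanism: the
#' feature map is globally max-pooled and average-pooled to two length-C
#' descriptors, each is passed through one shared two-layer ReLU MLP, the two
#' outputs are summed, and a sigmoid maps the result into (0, 1).
#'
#' @param f Numeric array of dim (C, H, W) with finite entries.
#' @param reduction_ratio Positive integer bottleneck ratio of the MLP.
#' @param params Optional CBAM parameter object from [cbam_params()]; when
#'   `NULL`, fresh parameters are drawn (seeded if `seed` is given).
#' @param seed Optional seed for parameter initialization.
#' @return Numeric vector of length C with entries strictly in (0, 1).
#' @examples
#' f <- array(runif(2 * 4 * 4), c(2, 4, 4))
#' w <- channel_attention(f, reduction_ratio = 2, seed = 1)
#' stopifnot(length(w) == 2, all(w > 0 & w < 1))
#' @export
channel_attention <- function(f, reduction_ratio = 16L, params = NULL,
                              seed = NULL) {
  validate_feature_map(f)
  if (reduction_ratio < 1L) {
    stop("reduction_ratio must be a positive integer", call. = FALSE)
  }
  if (is.null(params)) {
    params <- cbam_params(dim(f)[1], reduction_ratio, seed = seed)
  }
  ca <- channel_att_fwd(params, as_batch(f))
  as.vector(ca$s)
}

#' Spatial attention weights of a feature map
#'
#' Computes the per-pixel gate of the spatial attention mechanism: channel-wise
#' max and mean maps (each 1 x H x W) are concatenated to a 2-channel map,
#' reduced to one channel by a single `kernel_size` x `kernel_size` convolution
#' with "same" edge-replicate padding, and squashed by a sigmoid. Replicate
#' (rather than zero) padding makes the gate of a spatially constant input
#' uniform all the way to the borders.
#'
#' @inheritParams channel_attention
#' @param kernel_size Odd positive convolution size (default 7).
#' @return Numeric array of dim (H, W) with entries strictly in (0, 1).
#' @export
spatial_attention <- function(f, kernel_size = 7L, params = NULL,
                              seed = NULL) {
  validate_feature_map(f)
  if (kernel_size %% 2L != 1L || kernel_size < 1L) {
    stop("kernel_size must be an odd positive integer", call. = FALSE)
  }
  if (is.null(params)) {
    params <- cbam_params(dim(f)[1], spatial_kernel = kernel_size, seed = seed)
  }
  sa <- spatial_att_fwd(params, as_batch(f))
  array(sa$m, dim(f)[2:3])
}

#' Convolutional block attention (CBAM) gating of a feature map
#'
#' Applies channel attention first, then spatial attention, each as a
#' multiplicative gate: `f1 = f * channel_gate` (broadcast over space) and
#' `f2 = f1 * spatial_gate` (broadcast over channels). The output has the same
#' shape as the input, and since both gates lie in (0, 1) the output never
#' exceeds the input in absolute value.
#'
#' @inheritParams channel_attention
#' @param spatial_kernel Odd kernel size of the spatial-attention convolution.
#' @return Numeric array with the same dim as `f`.
#' @examples
#' f <- array(rnorm(3 * 5 * 5), c(3, 5, 5))
#' g <- cbam(f, reduction_ratio = 2, seed = 7)
#' stopifnot(identical(dim(g), dim(f)), all(abs(g) <= abs(f)))
#' @export
cbam <- function(f, reduction_ratio = 16L, spatial_kernel = 7L,
                 params = NULL, seed = NULL) {
  validate_feature_map(f)
  if (is.null(params)) {
    params <- cbam_params(dim(f)[1], reduction_ratio, spatial_kernel,
                          seed = seed)
  }
  out <- cbam_forward(params, as_batch(f))
  from_batch(out$y)
}
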