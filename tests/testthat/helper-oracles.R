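# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles are deliberately naive R implementations that share no
# code with the package's computational path.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive dilated 2-D convolution on a single (C, H, W) map with a
# (Co, Ci, k, k) kernel, zero padding `pad`, stride 1.
brute_conv2d <- function(x, w, pad = 0L, dil = 1L) {
  d <- dim(x)
  kd <- dim(w)
  h_out <- d[2] + 2 * pad - dil * (kd[3] - 1)
  w_out <- d[3] + 2 * pad - dil * (kd[4] - 1)
  out <- array(0, c(kd[1], h_out, w_out))
  for (co in seq_len(kd[1])) {
    for (ho in seq_len(h_out)) {
      for (wo in seq_len(w_out)) {
        acc <- 0
        for (ci in seq_len(kd[2])) {
          for (kh in seq_len(kd[3])) {
            for (kw in seq_len(kd[4])) {
              hi <- ho - pad + (kh - 1) * dil
              wi <- wo - pad + (kw - 1) * dil
              if (hi >= 1 && hi <= d[2] && wi >= 1 && wi <= d[3]) {
                acc <- acc + x[ci, hi, wi] * w[co, ci, kh, kw]
              }
            }
          }
        }
        out[co, ho, wo] <- acc
      }
    }
  }
  out
}

# Edge-replicate padding of a (C, H, W) map by p pixels.
brute_replicate_pad <- function(x, p) {
  d <- dim(x)
  ih <- pmin(pmax(seq_len(d[2] + 2 * p) - p, 1), d[2])
  iw <- pmin(pmax(seq_len(d[3] + 2 * p) - p, 1), d[3])
  x[, ih, iw, drop = FALSE]
}

# Side length of the bounding box of nonzero entries of a matrix.
footprint_side <- function(m, tol = 1e-12) {
  nz <- which(abs(m) > tol, arr.ind = TRUE)
  if (nrow(nz) == 0) return(0L)
  max(max(nz[, 1]) - min(nz[, 1]), max(nz[, 2]) - min(nz[, 2])) + 1L
}

# CBAM parameters with every trainable weight zero (gates become sigmoid(0)).
zero_cbam_params <- function(c_ch, reduction_ratio = 16L, spatial_kernel = 7L) {
  p <- cbam_params(c_ch, reduction_ratio, spatial_kernel, seed = 1)
  p$params <- lapply(p$params, function(a) a * 0)
  p
}

# Numeric central-difference gradient of a scalar function.
num_grad <- function(fun, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  g
}

# A uniform 8-bit test image.
flat_image <- function(h, w, rgb = c(100, 100, 100)) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Manifest of synthetic records without any backing files (for counting and
# splitting logic that never touches pixels).
fake_manifest <- function(labels) {
  df <- data.frame(path = sprintf("img_%05d.png", seq_along(labels)),
                   label = labels, provenance = "original")
  msfnet:::new_manifest(df, sort(unique(labels)))
}

# Shared tiny synthetic image folder, generated once per test run.
tiny_dataset_dir <- local({
  cache <- NULL
  function(n_per_class = 4, size = 32, seed = 101) {
    key <- sprintf("synth_%d_%d_%d", n_per_class, size, seed)
    dir <- file.path(tempdir(), key)
    if (!dir.exists(dir)) {
      generate_synthetic_dataset(dir, n_per_class = n_per_class,
                                 image_size = c(size, size), seed = seed)
    }
    dir
  }
})

tiny_model_config <- function(num_classes = 5, resolution = 32) {
  backbone_config(num_classes = num_classes, resolution = resolution,
                  width_multiplier = 0.1, depth_multiplier = 0.1)
}
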