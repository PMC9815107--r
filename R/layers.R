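# Primitive trainable layers. Each layer is a list:
#   kind     one of "conv", "bn", "act", "gap", "dense" (composites elsewhere)
#   params   named list of numeric arrays (trainable)
#   buffers  named list of non-trainable state (batchnorm running stats)
#   cfg      static configuration
# layer_forward() returns list(y, cache, layer) -- the layer comes back so
# batchnorm can update its running statistics under R's copy semantics.
# layer_backward() returns list(dx, grads) with grads shaped like params.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

conv_make <- function(c_in, c_out, k = 3L, stride = 1L, pad = NULL,
                      dilation = 1L, bias = FALSE) {
  if (dilation < 1L) stop("dilation rate must be >= 1", call. = FALSE)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L * dilation
  params <- list(w = he_init(c(c_out, c_in, k, k), fan_in = c_in * k * k))
  if (bias) params$b <- numeric(c_out)
  structure(list(kind = "conv", params = params, buffers = list(),
                 cfg = list(stride = as.integer(stride),
                            pad = as.integer(pad),
                            dilation = as.integer(dilation),
                            bias = bias)),
            class = "msf_layer")
}

bn_make <- function(c_ch, momentum = 0.1, eps = 1e-5) {
  structure(list(kind = "bn",
                 params = list(gamma = rep(1, c_ch), beta = rep(0, c_ch)),
                 buffers = list(running_mean = rep(0, c_ch),
                                running_var = rep(1, c_ch)),
                 cfg = list(momentum = momentum, eps = eps)),
            class = "msf_layer")
}

act_make <- function(fun = c("swish", "relu", "sigmoid")) {
  fun <- match.arg(fun)
  structure(list(kind = "act", params = list(), buffers = list(),
                 cfg = list(fun = fun)),
            class = "msf_layer")
}

gap_make <- function() {
  structure(list(kind = "gap", params = list(), buffers = list(), cfg = list()),
            class = "msf_layer")
}

dense_make <- function(c_in, c_out) {
  structure(list(kind = "dense",
                 params = list(w = he_init(c(c_out, c_in), fan_in = c_in),
                               b = numeric(c_out)),
                 buffers = list(), cfg = list()),
            class = "msf_layer")
}

conv_forward <- function(layer, x) {
  b <- if (isTRUE(layer$cfg$bias)) layer$params$b else numeric(0)
  y <- conv2d_fwd_cpp(x, layer$params$w, b,
                      layer$cfg$stride, layer$cfg$pad, layer$cfg$dilation)
  list(y = y, cache = list(x = x))
}

conv_backward <- function(layer, cache, dy) {
  g <- conv2d_bwd_cpp(cache$x, layer$params$w, dy,
                      layer$cfg$stride, layer$cfg$pad, layer$cfg$dilation,
                      isTRUE(layer$cfg$bias))
  grads <- list(w = g$dw)
  if (isTRUE(layer$cfg$bias)) grads$b <- g$db
  list(dx = g$dx, grads = grads)
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  eps <- layer$cfg$eps
  if (training) {
    mom <- channel_moments(x)
    mu <- mom$mean
    v <- mom$var
    n_eff <- d[1] * d[3] * d[4]
    m <- layer$cfg$momentum
    layer$buffers$running_mean <- (1 - m) * layer$buffers$running_mean + m * mu
    # unbiased variance for the running buffer, as is conventional
    vu <- if (n_eff > 1) v * n_eff / (n_eff - 1) else v
    layer$buffers$running_var <- (1 - m) * layer$buffers$running_var + m * vu
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  invstd <- 1 / sqrt(v + eps)
  # broadcast per-channel values over (n, h, w) via length-N*C recycling
  bc <- function(per_ch) as.vector(matrix(per_ch, d[1], d[2], byrow = TRUE))
  xhat <- (x - bc(mu)) * bc(invstd)
  y <- xhat * bc(layer$params$gamma) + bc(layer$params$beta)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, training = training),
       layer = layer)
}

bn_backward <- function(layer, cache, dy) {
  d <- dim(dy)
  xhat <- cache$xhat
  # per-channel reductions over (n, h, w)
  red <- function(z) {
    zp <- aperm(z, c(2L, 1L, 3L, 4L))
    dim(zp) <- c(d[2], d[1] * d[3] * d[4])
    rowSums(zp)
  }
  dgamma <- red(dy * xhat)
  dbeta <- red(dy)
  g_nc <- matrix(layer$params$gamma, d[1], d[2], byrow = TRUE)
  dxhat <- scale_nc(dy, g_nc)
  is_nc <- matrix(cache$invstd, d[1], d[2], byrow = TRUE)
  if (isTRUE(cache$training)) {
    n_eff <- d[1] * d[3] * d[4]
    s1 <- matrix(red(dxhat), d[1], d[2], byrow = TRUE)
    s2 <- matrix(red(dxhat * xhat), d[1], d[2], byrow = TRUE)
    dx <- scale_nc(dxhat - scale_nc(array(1, d), s1) / n_eff -
                     xhat * as.vector(s2) / n_eff, is_nc)
  } else {
    dx <- scale_nc(dxhat, is_nc)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

act_forward <- function(layer, x) {
  y <- switch(layer$cfg$fun,
              swish = swish(x), relu = relu(x), sigmoid = sigmoid(x))
  list(y = y, cache = list(x = x, y = y))
}

act_backward <- function(layer, cache, dy) {
  dx <- switch(layer$cfg$fun,
               swish = {
                 s <- sigmoid(cache$x)
                 dy * (s + cache$x * s * (1 - s))
               },
               relu = dy * (cache$x > 0),
               sigmoid = dy * cache$y * (1 - cache$y))
  list(dx = dx, grads = list())
}

gap_forward <- function(layer, x) {
  d <- dim(x)
  y <- sum_spatial(x) / (d[3] * d[4])
  list(y = y, cache = list(dims = d))
}

gap_backward <- function(layer, cache, dy) {
  d <- cache$dims
  dx <- array(0, d)
  dx <- dx + as.vector(dy) / (d[3] * d[4])
  list(dx = dx, grads = list())
}

dense_forward <- function(layer, x) {
  y <- x %*% t(layer$params$w)
  y <- sweep(y, 2L, layer$params$b, "+")
  list(y = y, cache = list(x = x))
}

dense_backward <- function(layer, cache, dy) {
  list(dx = dy %*% layer$params$w,
       grads = list(w = t(dy) %*% cache$x, b = colSums(dy)))
}

layer_forward <- function(layer, x, training = FALSE) {
  out <- switch(layer$kind,
                conv = conv_forward(layer, x),
                bn = bn_forward(layer, x, training),
                act = act_forward(layer, x),
                gap = gap_forward(layer, x),
                dense = dense_forward(layer, x),
                cbam = cbam_forward(layer, x),
                msfm = msfm_forward_layer(layer, x, training),
                stop("unknown layer kind: ", layer$kind))
  if (is.null(out$layer)) out$layer <- layer
  out
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
         conv = conv_backward(layer, cache, dy),
         bn = bn_backward(layer, cache, dy),
         act = act_backward(layer, cache, dy),
         gap = gap_backward(layer, cache, dy),
         dense = dense_backward(layer, cache, dy),
         cbam = cbam_backward(layer, cache, dy),
         msfm = msfm_backward_layer(layer, cache, dy),
         stop("unknown layer kind: ", layer$kind))
}

# ---- parameter traversal -------------------------------------------------
# Layers may hold child layers (composites store them under $children); these
# helpers give a uniform nested view of all trainable arrays.

layer_params <- function(layer) {
  p <- layer$params
  if (!is.null(layer$children)) {
    p$children <- lapply(layer$children, layer_params)
  }
  p
}

layer_set_params <- function(layer, p) {
  kids <- p$children
  p$children <- NULL
  layer$params <- p
  if (!is.null(kids)) {
    for (nm in names(kids)) {
      layer$children[[nm]] <- layer_set_params(layer$children[[nm]], kids[[nm]])
    }
  }
  layer
}

layer_buffers <- function(layer) {
  b <- layer$buffers
  if (!is.null(layer$children)) {
    b$children <- lapply(layer$children, layer_buffers)
  }
  b
}

layer_set_buffers <- function(layer, b) {
  kids <- b$children
  b$children <- NULL
  layer$buffers <- b
  if (!is.null(kids)) {
    for (nm in names(kids)) {
      layer$children[[nm]] <-
        layer_set_buffers(layer$children[[nm]], kids[[nm]])
    }
  }
  layer
}

# Apply f(leaf1, leaf2, ...) over parallel nested lists of numeric arrays.
param_map <- function(f, ...) {
  lists <- list(...)
  p1 <- lists[[1]]
  if (is.numeric(p1)) {
    return(do.call(f, lists))
  }
  out <- p1
  for (nm in names(p1)) {
    out[[nm]] <- do.call(param_map, c(list(f), lapply(lists, `[[`, nm)))
  }
  out
}

param_count <- function(p) {
  if (is.numeric(p)) return(length(p))
  as.integer(sum(vapply(p, param_count, numeric(1))))
}

# Edge-replicate padding of an (N,C,H,W) batch by p pixels, and its adjoint
# (gradients of replicated border pixels accumulate onto their source).
replicate_pad <- function(x, p) {
  d <- dim(x)
  ih <- pmin(pmax(seq_len(d[3] + 2L * p) - p, 1L), d[3])
  iw <- pmin(pmax(seq_len(d[4] + 2L * p) - p, 1L), d[4])
  x[, , ih, iw, drop = FALSE]
}

replicate_pad_backward <- function(dpad, p, h, w) {
  d <- dim(dpad)
  ih <- pmin(pmax(seq_len(h + 2L * p) - p, 1L), h)
  iw <- pmin(pmax(seq_len(w + 2L * p) - p, 1L), w)
  tmp <- array(0, c(d[1], d[2], h, d[4]))
  for (i in seq_along(ih)) {
    tmp[, , ih[i], ] <- tmp[, , ih[i], ] + dpad[, , i, ]
  }
  dx <- array(0, c(d[1], d[2], h, w))
  for (j in seq_along(iw)) {
    dx[, , , iw[j]] <- dx[, , , iw[j]] + tmp[, , , j]
  }
  dx
}
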