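# Multi-scale fusion module: CBAM recalibration feeding parallel dilated 3x3
# convolution branches (rates 1, 2, 4 by default), channel-concatenated and
# reduced back by a 1x1 convolution. Each branch zero-pads by its dilation
# rate so all branch outputs keep the input's spatial extent and can be fused.

#' Expanded kernel side of a dilated convolution
#'
#' A k x k kernel with dilation rate r places its taps r pixels apart, so the
#' bounding box of its tap positions has side `k + (k - 1) * (r - 1)`. A 3x3
#' kernel at rate 2 therefore covers the same 5x5 region as an ordinary 5x5
#' kernel while keeping only 9 trainable weights.
#'
#' @param k Odd positive kernel side length.
#' @param r Positive integer dilation (expansion) rate.
#' @return The expanded side length, a positive integer.
#' @examples
#' dilated_kernel_size(3, 2)  # 5
#' dilated_kernel_size(3, 1)  # 3: rate 1 is ordinary convolution
#' @export
dilated_kernel_size <- function(k, r) {
  if (any(k < 1) || any(r < 1)) {
    stop("k and r must be positive integers", call. = FALSE)
  }
  k + (k - 1) * (r - 1)
}

#' One dilated 3x3 convolution branch
#'
#' Applies a 3x3 convolution with dilation rate `r` and zero padding `r` on
#' each side, preserving the spatial extent. The kernel keeps 9 taps per
#' input/output channel pair regardless of `r`; only the spacing of the taps
#' (and hence the receptive field) grows.
#'
#' @param f Numeric array of dim (C, H, W).
#' @param out_channels Number of output channels.
#' @param r Positive integer dilation rate.
#' @param params Optional conv layer from a previous call (field `w` of dim
#'   `(out_channels, C, 3, 3)`); when `NULL` fresh weights are drawn.
#' @param seed Optional seed for initialization.
#' @return Numeric array of dim (out_channels, H, W).
#' @export
dilated_branch <- function(f, out_channels, r, params = NULL, seed = NULL) {
  validate_feature_map(f)
  if (r < 1) stop("dilation rate r must be >= 1", call. = FALSE)
  if (is.null(params)) {
    make <- function() conv_make(dim(f)[1], out_channels, k = 3L,
                                 stride = 1L, pad = r, dilation = r)
    params <- if (is.null(seed)) make() else with_seed(seed, make())
  }
  out <- conv_forward(params, as_batch(f))
  from_batch(out$y)
}

msfm_make <- function(c_in, c_branch = NULL, c_out = NULL,
                      rates = c(1L, 2L, 4L), reduction_ratio = 16L,
                      spatial_kernel = 7L, norm_act = TRUE,
                      fusion = c("concat", "sum")) {
  fusion <- match.arg(fusion)
  if (is.null(c_branch)) c_branch <- c_in
  if (is.null(c_out)) c_out <- c_in
  children <- list(cbam = cbam_make(c_in, reduction_ratio, spatial_kernel))
  for (i in seq_along(rates)) {
    r <- as.integer(rates[i])
    children[[paste0("branch", r)]] <-
      conv_make(c_in, c_branch, k = 3L, stride = 1L, pad = r, dilation = r)
    if (norm_act) {
      children[[paste0("branch", r, "_bn")]] <- bn_make(c_branch)
    }
  }
  c_fused <- if (fusion == "concat") length(rates) * c_branch else c_branch
  children$reduce <- conv_make(c_fused, c_out, k = 1L, stride = 1L, pad = 0L)
  if (norm_act) children$reduce_bn <- bn_make(c_out)
  structure(list(kind = "msfm", params = list(), buffers = list(),
                 children = children,
                 cfg = list(c_in = c_in, c_branch = c_branch, c_out = c_out,
                            rates = as.integer(rates), norm_act = norm_act,
                            fusion = fusion)),
            class = "msf_layer")
}

msfm_forward_layer <- function(layer, x, training = FALSE) {
  cfg <- layer$cfg
  caches <- list()
  g <- layer_forward(layer$children$cbam, x)
  caches$cbam <- g$cache
  feat <- g$y
  d <- dim(feat)

  branch_out <- vector("list", length(cfg$rates))
  for (i in seq_along(cfg$rates)) {
    r <- cfg$rates[i]
    nm <- paste0("branch", r)
    b <- layer_forward(layer$children[[nm]], feat)
    caches[[nm]] <- b$cache
    y <- b$y
    if (cfg$norm_act) {
      nb <- paste0(nm, "_bn")
      bn <- layer_forward(layer$children[[nb]], y, training)
      layer$children[[nb]] <- bn$layer
      caches[[nb]] <- bn$cache
      caches[[paste0(nm, "_pre")]] <- bn$y
      y <- swish(bn$y)
    }
    branch_out[[i]] <- y
  }

  if (cfg$fusion == "concat") {
    fused <- array(0, c(d[1], length(cfg$rates) * cfg$c_branch, d[3], d[4]))
    for (i in seq_along(branch_out)) {
      fused[, (i - 1L) * cfg$c_branch + seq_len(cfg$c_branch), , ] <-
        branch_out[[i]]
    }
  } else {
    fused <- Reduce(`+`, branch_out)
  }

  red <- layer_forward(layer$children$reduce, fused)
  caches$reduce <- red$cache
  y <- red$y
  if (cfg$norm_act) {
    bn <- layer_forward(layer$children$reduce_bn, y, training)
    layer$children$reduce_bn <- bn$layer
    caches$reduce_bn <- bn$cache
    caches$reduce_pre <- bn$y
    y <- swish(bn$y)
  }
  list(y = y, cache = caches, layer = layer)
}

msfm_backward_layer <- function(layer, cache, dy) {
  cfg <- layer$cfg
  grads <- list(children = list())

  if (cfg$norm_act) {
    pre <- cache$reduce_pre
    s <- sigmoid(pre)
    dy <- dy * (s + pre * s * (1 - s))
    bnb <- layer_backward(layer$children$reduce_bn, cache$reduce_bn, dy)
    grads$children$reduce_bn <- bnb$grads
    dy <- bnb$dx
  }
  rb <- layer_backward(layer$children$reduce, cache$reduce, dy)
  grads$children$reduce <- rb$grads
  dfused <- rb$dx

  d <- dim(dfused)
  dfeat <- NULL
  for (i in seq_along(cfg$rates)) {
    r <- cfg$rates[i]
    nm <- paste0("branch", r)
    if (cfg$fusion == "concat") {
      dbr <- dfused[, (i - 1L) * cfg$c_branch + seq_len(cfg$c_branch), , ,
                    drop = FALSE]
    } else {
      dbr <- dfused
    }
    if (cfg$norm_act) {
      pre <- cache[[paste0(nm, "_pre")]]
      s <- sigmoid(pre)
      dbr <- dbr * (s + pre * s * (1 - s))
      nb <- paste0(nm, "_bn")
      bnb <- layer_backward(layer$children[[nb]], cache[[nb]], dbr)
      grads$children[[nb]] <- bnb$grads
      dbr <- bnb$dx
    }
    cb <- layer_backward(layer$children[[nm]], cache[[nm]], dbr)
    grads$children[[nm]] <- cb$grads
    dfeat <- if (is.null(dfeat)) cb$dx else dfeat + cb$dx
  }

  cbb <- layer_backward(layer$children$cbam, cache$cbam, dfeat)
  grads$children$cbam <- cbb$grads
  list(dx = cbb$dx, grads = grads)
}

#' Multi-scale fusion module forward pass
#'
#' Runs one feature map through the multi-scale fusion module: CBAM channel
#' and spatial recalibration, then parallel dilated 3x3 branches at the
#' configured rates (default 1, 2, 4), fused by channel concatenation and a
#' 1x1 reduction convolution. The spatial extent is preserved; the channel
#' count becomes `c_out`.
#'
#' @param f Numeric array of dim (C, H, W).
#' @param params Optional module object from [msfm_params()]; fresh parameters
#'   are drawn when `NULL`.
#' @param c_branch,c_out Branch width and output width (default both C, making
#'   the module drop-in shape-preserving).
#' @param rates Integer vector of dilation rates.
#' @param norm_act Apply batch-style normalization and swish after each
#'   convolution (`TRUE`, the backbone convention) or leave branches linear.
#' @param fusion `"concat"` (concatenate then 1x1-reduce, the default) or
#'   `"sum"` (elementwise sum of equally wide branches then 1x1-reduce).
#' @param seed Optional seed for initialization.
#' @return Numeric array of dim (c_out, H, W).
#' @export
msfm_forward <- function(f, params = NULL, c_branch = NULL, c_out = NULL,
                         rates = c(1L, 2L, 4L), norm_act = TRUE,
                         fusion = "concat", seed = NULL) {
  validate_feature_map(f)
  if (is.null(params)) {
    params <- msfm_params(dim(f)[1], c_branch, c_out, rates = rates,
                          norm_act = norm_act, fusion = fusion, seed = seed)
  }
  if (params$cfg$c_in != dim(f)[1]) {
    stop(sprintf("msfm configured for %d input channels, got %d",
                 params$cfg$c_in, dim(f)[1]), call. = FALSE)
  }
  out <- msfm_forward_layer(params, as_batch(f), training = FALSE)
  from_batch(out$y)
}

#' Create parameters for a multi-scale fusion module
#'
#' @inheritParams msfm_forward
#' @param c_in Input channel count.
#' @param reduction_ratio,spatial_kernel CBAM configuration, see
#'   [cbam_params()].
#' @return An MSFM layer object for [msfm_forward()].
#' @export
msfm_params <- function(c_in, c_branch = NULL, c_out = NULL,
                        rates = c(1L, 2L, 4L), reduction_ratio = 16L,
                        spatial_kernel = 7L, norm_act = TRUE,
                        fusion = "concat", seed = NULL) {
  make <- function() msfm_make(c_in, c_branch, c_out, rates, reduction_ratio,
                               spatial_kernel, norm_act, fusion)
  if (is.null(seed)) make() else with_seed(seed, make())
}
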