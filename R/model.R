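# Classifier assembly: an EfficientNet-B6-shaped backbone (stage table of
# widths/depths/strides) whose shallow feature stream is replaced by the
# multi-scale fusion module, with CBAM recalibration at the end of every
# later stage, global average pooling and a K-way linear head. Stages are
# built from conv3x3 -> batchnorm -> swish blocks following the B6 stage
# layout; width and depth multipliers shrink the same table to test scale.

b6_stage_table <- function() {
  list(widths = c(32L, 40L, 72L, 144L, 200L, 344L, 576L),
       depths = c(3L, 6L, 6L, 8L, 9L, 11L, 3L),
       strides = c(1L, 2L, 2L, 2L, 1L, 2L, 1L),
       stem_width = 56L, head_width = 2304L)
}

scale_width <- function(w, mult) {
  pmax(4L, as.integer(round(w * mult / 4) * 4))
}

scale_depth <- function(d, mult) {
  pmax(1L, as.integer(ceiling(d * mult)))
}

#' Backbone configuration
#'
#' Describes the full classifier: a B6-shaped stage table (widths, depths,
#' strides), the input resolution, the class count, where the multi-scale
#' fusion module is inserted, and which stages receive CBAM recalibration.
#'
#' @param num_classes Number of output classes K (>= 2, default 5).
#' @param resolution Square input resolution in pixels (>= 32, default 224).
#' @param width_multiplier,depth_multiplier Scale factors applied to the stage
#'   widths/depths for test-scale models (default 1 = full B6 shape).
#' @param msfm_stage Stage index after which the MSFM replaces the shallow
#'   feature stream (default 2); `use_msfm = FALSE` removes the module.
#' @param cbam_stages Integer vector of stage indices whose final block gets a
#'   CBAM gate immediately before its normalization; default: every stage
#'   after `msfm_stage`.
#' @param cbam_reduction,spatial_kernel CBAM hyperparameters.
#' @param msfm_rates Dilation rates of the fusion branches (default 1, 2, 4).
#' @param msfm_fusion `"concat"` or `"sum"` branch fusion.
#' @param use_msfm Include the multi-scale fusion module (default `TRUE`).
#' @return A `backbone_config` object for [build_model()].
#' @export
backbone_config <- function(num_classes = 5L, resolution = 224L,
                            width_multiplier = 1, depth_multiplier = 1,
                            msfm_stage = 2L, cbam_stages = NULL,
                            cbam_reduction = 16L, spatial_kernel = 7L,
                            msfm_rates = c(1L, 2L, 4L),
                            msfm_fusion = "concat", use_msfm = TRUE) {
  tab <- b6_stage_table()
  n_stage <- length(tab$widths)
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  if (resolution < 32L) stop("resolution must be >= 32", call. = FALSE)
  if (msfm_stage < 1L || msfm_stage > n_stage) {
    stop("msfm_stage must index a backbone stage (1..", n_stage, ")",
         call. = FALSE)
  }
  if (is.null(cbam_stages)) {
    cbam_stages <- if (msfm_stage < n_stage) (msfm_stage + 1L):n_stage
                   else integer(0)
  }
  if (length(cbam_stages) && (min(cbam_stages) < 1L ||
                              max(cbam_stages) > n_stage)) {
    stop("cbam_stages out of stage range", call. = FALSE)
  }
  structure(list(num_classes = as.integer(num_classes),
                 resolution = as.integer(resolution),
                 width_multiplier = width_multiplier,
                 depth_multiplier = depth_multiplier,
                 widths = scale_width(tab$widths, width_multiplier),
                 depths = scale_depth(tab$depths, depth_multiplier),
                 strides = tab$strides,
                 stem_width = scale_width(tab$stem_width, width_multiplier),
                 head_width = scale_width(tab$head_width, width_multiplier),
                 msfm_stage = as.integer(msfm_stage),
                 cbam_stages = as.integer(cbam_stages),
                 cbam_reduction = as.integer(cbam_reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 msfm_rates = as.integer(msfm_rates),
                 msfm_fusion = msfm_fusion,
                 use_msfm = isTRUE(use_msfm)),
            class = "backbone_config")
}

#' Build the multi-scale fusion classifier
#'
#' Assembles stem, backbone stages, the MSFM insertion, CBAM-gated later
#' stages, head convolution, global average pooling and the K-way linear
#' classifier. Initialization is deterministic given `seed`.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed controlling parameter initialization.
#' @return An object of class `msf_model`.
#' @export
build_model <- function(config = backbone_config(), seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  layers <- with_seed(seed, {
    ly <- list()
    ly$stem_conv <- conv_make(3L, config$stem_width, k = 3L, stride = 2L)
    ly$stem_bn <- bn_make(config$stem_width)
    ly$stem_act <- act_make("swish")
    c_prev <- config$stem_width
    for (s in seq_along(config$widths)) {
      w <- config$widths[s]
      for (b in seq_len(config$depths[s])) {
        stride <- if (b == 1L) config$strides[s] else 1L
        nm <- sprintf("s%d_b%d", s, b)
        ly[[paste0(nm, "_conv")]] <- conv_make(c_prev, w, k = 3L,
                                               stride = stride)
        last <- b == config$depths[s]
        if (last && s %in% config$cbam_stages) {
          ly[[paste0(nm, "_cbam")]] <-
            cbam_make(w, config$cbam_reduction, config$spatial_kernel)
        }
        ly[[paste0(nm, "_bn")]] <- bn_make(w)
        ly[[paste0(nm, "_act")]] <- act_make("swish")
        c_prev <- w
      }
      if (config$use_msfm && s == config$msfm_stage) {
        ly$msfm <- msfm_make(c_prev, reduction_ratio = config$cbam_reduction,
                             spatial_kernel = config$spatial_kernel,
                             rates = config$msfm_rates,
                             fusion = config$msfm_fusion)
      }
    }
    ly$head_conv <- conv_make(c_prev, config$head_width, k = 1L, pad = 0L)
    ly$head_bn <- bn_make(config$head_width)
    ly$head_act <- act_make("swish")
    ly$gap <- gap_make()
    ly$fc <- dense_make(config$head_width, config$num_classes)
    ly
  })
  structure(list(config = config, layers = layers, seed = as.integer(seed),
                 classes = NULL, norm_stats = NULL),
            class = "msf_model")
}

# Full forward pass. Returns logits, per-layer caches (for backward) and the
# possibly updated model (batchnorm running stats).
model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  names(caches) <- names(model$layers)
  for (nm in names(model$layers)) {
    out <- layer_forward(model$layers[[nm]], x, training)
    model$layers[[nm]] <- out$layer
    caches[[nm]] <- out$cache
    x <- out$y
  }
  list(logits = x, caches = caches, model = model)
}

# Backward pass from a logits gradient. Returns grads per layer and, when
# `boundary` names a layer, the gradient with respect to that layer's output
# (used by Grad-CAM).
model_backward <- function(model, caches, dlogits, boundary = NULL) {
  grads <- vector("list", length(model$layers))
  names(grads) <- names(model$layers)
  dy <- dlogits
  boundary_grad <- NULL
  for (nm in rev(names(model$layers))) {
    if (!is.null(boundary) && nm == boundary) boundary_grad <- dy
    bk <- layer_backward(model$layers[[nm]], caches[[nm]], dy)
    grads[[nm]] <- bk$grads
    dy <- bk$dx
  }
  list(grads = grads, dinput = dy, boundary_grad = boundary_grad)
}

model_params <- function(model) lapply(model$layers, layer_params)

model_set_params <- function(model, params) {
  for (nm in names(params)) {
    model$layers[[nm]] <- layer_set_params(model$layers[[nm]], params[[nm]])
  }
  model
}

model_buffers <- function(model) lapply(model$layers, layer_buffers)

model_set_buffers <- function(model, buffers) {
  for (nm in names(buffers)) {
    model$layers[[nm]] <- layer_set_buffers(model$layers[[nm]], buffers[[nm]])
  }
  model
}

#' Number of trainable parameters
#'
#' @param model An `msf_model`, or a single layer object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "msf_model")) {
    return(as.integer(sum(vapply(
      model$layers, function(l) param_count(layer_params(l)), numeric(1)))))
  }
  param_count(layer_params(model))
}

#' Class probabilities for a preprocessed image batch
#'
#' Runs the forward pass in evaluation mode and applies a softmax, so each
#' row is a probability vector over the K classes summing to 1.
#'
#' @param object An `msf_model`.
#' @param images Numeric array of dim (N, 3, resolution, resolution), already
#'   preprocessed (see [preprocess_images()]).
#' @param ... Unused.
#' @return Matrix of dim (N, K) of class probabilities.
#' @export
predict.msf_model <- function(object, images, ...) {
  if (length(dim(images)) == 3L) images <- as_batch(images)
  d <- dim(images)
  res <- object$config$resolution
  if (length(d) != 4L || d[2] != 3L || d[3] != res || d[4] != res) {
    stop(sprintf(
      "images must be a (N, 3, %d, %d) array matching the model resolution",
      res, res), call. = FALSE)
  }
  logits <- model_forward(object, images, training = FALSE)$logits
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  colnames(probs) <- object$classes
  probs
}

#' @export
print.msf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("msf_model: %d classes, resolution %d, width x%.2g, depth x%.2g\n",
              cfg$num_classes, cfg$resolution, cfg$width_multiplier,
              cfg$depth_multiplier))
  cat(sprintf("  msfm: %s (after stage %d, rates %s); cbam stages: %s\n",
              if (cfg$use_msfm) "yes" else "no", cfg$msfm_stage,
              paste(cfg$msfm_rates, collapse = "/"),
              paste(cfg$cbam_stages, collapse = ",")))
  cat(sprintf("  parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- checkpoints ---------------------------------------------------------

config_to_list <- function(cfg) {
  keep <- c("num_classes", "resolution", "width_multiplier",
            "depth_multiplier", "msfm_stage", "cbam_stages",
            "cbam_reduction", "spatial_kernel", "msfm_rates", "msfm_fusion",
            "use_msfm")
  cfg[keep]
}

config_from_list <- function(lst) {
  do.call(backbone_config, lapply(lst, function(v) {
    if (is.list(v)) unlist(v) else v
  }))
}

#' Save / load model checkpoints
#'
#' The checkpoint stores parameters and batchnorm buffers in R's native
#' serialized format; a JSON sidecar (`<path>.json`) records the architecture
#' configuration, class vocabulary and normalization statistics, so the model
#' is reconstructible from the sidecar plus the weight file alone.
#'
#' @param model An `msf_model`.
#' @param path Checkpoint file path (the sidecar gets `.json` appended).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `msf_model`.
#' @export
save_checkpoint <- function(model, path) {
  sidecar <- list(package = "msfnet",
                  config = config_to_list(model$config),
                  seed = model$seed,
                  classes = model$classes,
                  norm_stats = model$norm_stats)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  saveRDS(list(params = model_params(model), buffers = model_buffers(model)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    stop("checkpoint or its .json sidecar not found at ", path, call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(side$package, "msfnet")) {
    stop("malformed checkpoint sidecar at ", sidecar_path, call. = FALSE)
  }
  cfg <- config_from_list(side$config)
  model <- build_model(cfg, seed = if (is.null(side$seed)) 0L else side$seed)
  state <- readRDS(path)
  model <- model_set_params(model, state$params)
  model <- model_set_buffers(model, state$buffers)
  model$classes <- side$classes
  if (!is.null(side$norm_stats) && length(side$norm_stats)) {
    model$norm_stats <- list(mean = as.numeric(side$norm_stats$mean),
                             sd = as.numeric(side$norm_stats$sd))
  }
  model
}
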