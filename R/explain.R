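# Grad-CAM explanations: the gradient of a target class logit with respect
# to a chosen spatial layer's activations is globally averaged into
# per-channel weights, the weighted activation sum is rectified, upsampled
# bilinearly to the image size and min-max normalized to [0, 1].

#' Grad-CAM heatmap for one image
#'
#' @param model A (typically trained) `msf_model`.
#' @param img H x W x 3 image array with values in 0..255.
#' @param target_class Class to explain: 1-based index or class name;
#'   `NULL` uses the predicted class.
#' @param layer Name of the layer whose output is explained (default
#'   `"msfm"`, the multi-scale fusion module; any convolutional stage name in
#'   `names(model$layers)` works). The layer must produce a spatial map.
#' @return An `msf_heatmap`: list with `values` (H x W in `[0, 1]`),
#'   `target_class`, `layer`, `constant` (TRUE when the raw map was flat and
#'   was normalized to all zeros).
#' @export
grad_cam <- function(model, img, target_class = NULL, layer = "msfm") {
  stopifnot(inherits(model, "msf_model"))
  validate_image(img)
  if (!layer %in% names(model$layers)) {
    stop("no layer named '", layer, "' in the model", call. = FALSE)
  }
  res <- model$config$resolution
  stats <- model$norm_stats
  if (is.null(stats)) stats <- list(mean = rep(0.5, 3), sd = rep(0.5, 3))
  x <- preprocess_images(img, res, stats)

  fw <- model_forward(model, x, training = FALSE)
  # locate the layer's activation from the cache of the layer that follows it
  nms <- names(model$layers)
  li <- match(layer, nms)
  act <- if (li < length(nms)) {
    nxt <- fw$caches[[nms[li + 1L]]]
    if (!is.null(nxt$x)) nxt$x else NULL
  } else NULL
  if (is.null(act)) {
    # recompute by forwarding up to the layer
    xx <- x
    for (nm in nms[seq_len(li)]) {
      xx <- layer_forward(model$layers[[nm]], xx, FALSE)$y
    }
    act <- xx
  }
  if (length(dim(act)) != 4L) {
    stop("layer '", layer, "' does not produce a spatial activation",
         call. = FALSE)
  }

  k <- model$config$num_classes
  logits <- fw$logits
  if (is.null(target_class)) {
    target_class <- which.max(logits[1L, ])
  } else if (is.character(target_class)) {
    idx <- match(target_class, model$classes)
    if (is.na(idx)) stop("unknown class: ", target_class, call. = FALSE)
    target_class <- idx
  }
  if (target_class < 1L || target_class > k) {
    stop("target_class out of range", call. = FALSE)
  }

  dlogits <- matrix(0, 1L, k)
  dlogits[1L, target_class] <- 1
  bw <- model_backward(model, fw$caches, dlogits, boundary = layer)
  grad <- bw$boundary_grad                        # (1, C, h, w)

  d <- dim(act)
  weights <- sum_spatial(grad)[1L, ] / (d[3] * d[4])  # per-channel alpha
  cam <- matrix(0, d[3], d[4])
  for (ci in seq_len(d[2])) {
    cam <- cam + weights[ci] * act[1L, ci, , ]
  }
  cam <- pmax(cam, 0)

  cam4 <- array(cam, c(1L, 1L, d[3], d[4]))
  up <- resize_bilinear_cpp(cam4, dim(img)[1], dim(img)[2])[1L, 1L, , ]
  rng <- range(up)
  constant <- (rng[2] - rng[1]) < 1e-12
  values <- if (constant) matrix(0, dim(img)[1], dim(img)[2])
            else (up - rng[1]) / (rng[2] - rng[1])
  structure(list(values = values, target_class = target_class,
                 layer = layer, constant = constant),
            class = "msf_heatmap")
}

heatmap_colormap <- function(values, colormap = "viridis") {
  pal <- grDevices::hcl.colors(256L, colormap)
  rgbm <- grDevices::col2rgb(pal)                 # 3 x 256
  idx <- pmin(pmax(floor(values * 255) + 1L, 1L), 256L)
  h <- nrow(values); w <- ncol(values)
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(rgbm[ch, idx], h, w)
  out
}

#' Overlay a heatmap on its source image
#'
#' The heatmap is mapped through a perceptually ordered colormap and
#' alpha-blended onto the image: `out = (1 - opacity) * img + opacity *
#' colormap(heatmap)`. Opacity 0 returns the image, opacity 1 the pure
#' colormap rendering.
#'
#' @param img H x W x 3 array, 0..255.
#' @param heatmap An `msf_heatmap` (or a bare H x W matrix in `[0, 1]`).
#' @param opacity Blend weight in `[0, 1]` (default 0.5).
#' @param colormap Palette name passed to `grDevices::hcl.colors`.
#' @return Blended H x W x 3 image array (0..255).
#' @export
overlay <- function(img, heatmap, opacity = 0.5, colormap = "viridis") {
  validate_image(img)
  values <- if (inherits(heatmap, "msf_heatmap")) heatmap$values else heatmap
  if (!all(dim(values) == dim(img)[1:2])) {
    stop("heatmap and image shapes disagree", call. = FALSE)
  }
  if (opacity < 0 || opacity > 1) {
    stop("opacity must lie in [0, 1]", call. = FALSE)
  }
  cmap <- heatmap_colormap(values, colormap)
  out <- (1 - opacity) * img + opacity * cmap
  out <- round(pmin(pmax(out, 0), 255))
  attr(out, "colormap") <- colormap
  out
}

#' Side-by-side explanation grid
#'
#' Writes a single PNG laying the original image next to one overlay per
#' model (e.g. baseline vs. multi-scale fusion model), mirroring the usual
#' qualitative comparison layout.
#'
#' @param img H x W x 3 array, 0..255.
#' @param overlays Named list of H x W x 3 overlay arrays.
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
save_comparison_grid <- function(img, overlays, file) {
  panels <- c(list(original = img), overlays)
  h <- dim(img)[1]
  sep <- 4L
  wtot <- sum(vapply(panels, function(p) dim(p)[2], numeric(1))) +
    sep * (length(panels) - 1L)
  grid <- array(255, c(h, wtot, 3L))
  at <- 1L
  for (p in panels) {
    w <- dim(p)[2]
    grid[, at:(at + w - 1L), ] <- p
    at <- at + w + sep
  }
  write_image(grid, file)
  invisible(file)
}
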