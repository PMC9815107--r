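# Cross-entropy and focal loss. Focal loss rescales the cross-entropy of each
# sample by (1 - p_t)^gamma, so confidently classified samples contribute
# little and training attention concentrates on hard ones; the per-class
# weight a_t additionally counters class imbalance. At gamma = 0 and a_t = 1
# the focal loss is exactly the cross-entropy.

.loss_eps <- 1e-7

clamp_pt <- function(p_t) {
  if (any(p_t <= 0)) {
    warning("p_t <= 0 clamped to ", .loss_eps, call. = FALSE)
  }
  pmin(pmax(p_t, .loss_eps), 1)
}

#' Weighted cross-entropy of true-class probabilities
#'
#' `CE(p_t) = -a_t * log(p_t)`, vectorised over `p_t`. Probabilities at or
#' below zero are clamped to a small epsilon (with a warning) so the result is
#' never NaN.
#'
#' @param p_t Predicted probability of the true class, in (0, 1].
#' @param a_t Positive class weight (scalar or vector recycled over `p_t`).
#' @return Nonnegative loss value(s).
#' @examples
#' cross_entropy(exp(-1))        # 1
#' cross_entropy(0.5, a_t = 2)   # 2 * log(2)
#' @export
cross_entropy <- function(p_t, a_t = 1) {
  stopifnot(all(a_t > 0))
  -a_t * log(clamp_pt(p_t))
}

#' Focal loss of true-class probabilities
#'
#' `FL(p_t) = -a_t * (1 - p_t)^gamma * log(p_t)`. The focusing exponent
#' `gamma >= 0` down-weights easy samples: the larger `gamma`, the smaller the
#' loss contribution of samples the model already classifies confidently.
#' `gamma = 0` with `a_t = 1` recovers [cross_entropy()] exactly.
#'
#' @inheritParams cross_entropy
#' @param gamma Nonnegative focusing exponent (default 2).
#' @return Nonnegative loss value(s), never exceeding the cross-entropy of the
#'   same `p_t` when `a_t` matches.
#' @examples
#' focal_loss(0.9, a_t = 0.25, gamma = 2)  # 0.25 * 0.01 * -log(0.9)
#' @export
focal_loss <- function(p_t, a_t = 1, gamma = 2) {
  stopifnot(all(a_t > 0), gamma >= 0)
  p <- clamp_pt(p_t)
  -a_t * (1 - p)^gamma * log(p)
}

#' Loss configuration
#'
#' @param kind `"focal"` or `"cross_entropy"`.
#' @param gamma Focusing exponent for focal loss (ignored for cross-entropy).
#' @param alpha Per-class weights: a positive vector of length K, a positive
#'   scalar, or `"inverse_frequency"` to derive weights from the training
#'   manifest as `N / (K * n_class)`.
#' @param reduction `"mean"`, `"sum"` or `"none"`.
#' @return A `loss_config` object.
#' @export
loss_config <- function(kind = c("focal", "cross_entropy"), gamma = 2,
                        alpha = "inverse_frequency",
                        reduction = c("mean", "sum", "none")) {
  kind <- match.arg(kind)
  reduction <- match.arg(reduction)
  if (is.numeric(alpha) && any(alpha <= 0)) {
    stop("alpha entries must be positive", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  structure(list(kind = kind, gamma = gamma, alpha = alpha,
                 reduction = reduction),
            class = "loss_config")
}

resolve_alpha <- function(cfg, labels, n_classes) {
  a <- cfg$alpha
  if (is.character(a)) {
    if (!identical(a, "inverse_frequency")) {
      stop("unknown alpha spec: ", a, call. = FALSE)
    }
    counts <- tabulate(labels, nbins = n_classes)
    counts[counts == 0] <- 1L
    a <- length(labels) / (n_classes * counts)
  }
  if (length(a) == 1L) a <- rep(a, n_classes)
  if (length(a) != n_classes) {
    stop("alpha must have one weight per class", call. = FALSE)
  }
  a
}

# Batch loss and its gradient with respect to logits. `labels` are 1-based
# class indices; `alpha` a resolved length-K vector.
softmax_loss_grad <- function(logits, labels, alpha, gamma = 2,
                              reduction = "mean") {
  n <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  ix <- cbind(seq_len(n), labels)
  p_t <- pmin(pmax(probs[ix], .loss_eps), 1)
  a_t <- alpha[labels]

  one_m <- 1 - p_t
  loss_i <- -a_t * one_m^gamma * log(p_t)
  # dL/dp_t; the gamma term vanishes identically at gamma = 0
  if (gamma > 0) {
    g <- a_t * (gamma * pmax(one_m, 1e-12)^(gamma - 1) * log(p_t) -
                  one_m^gamma / p_t)
  } else {
    g <- -a_t / p_t
  }
  # dp_t/dz_j = p_t (1[j = t] - p_j)
  dz <- -probs * (g * p_t)
  dz[ix] <- dz[ix] + g * p_t
  scale <- switch(reduction, mean = 1 / n, sum = 1, none = 1)
  loss <- switch(reduction,
                 mean = mean(loss_i), sum = sum(loss_i), none = loss_i)
  list(loss = loss, dlogits = dz * scale, probs = probs, p_t = p_t)
}
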