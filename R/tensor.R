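# Internal tensor helpers. Feature maps are numeric arrays of dim (C, H, W);
# batches are (N, C, H, W). R's column-major layout means an (N, C, H, W)
# batch multiplied by a length-N*C vector broadcasts that vector over every
# spatial position, which the attention code relies on.

sigmoid <- function(x) 1 / (1 + exp(-x))

swish <- function(x) x * sigmoid(x)

relu <- function(x) pmax(x, 0)

#' @noRd
validate_feature_map <- function(f, arg = "f") {
  if (!is.numeric(f) || length(dim(f)) != 3L) {
    stop(sprintf("`%s` must be a numeric array of dim (C, H, W)", arg),
         call. = FALSE)
  }
  if (any(dim(f) < 1L)) {
    stop(sprintf("`%s` must have C, H, W >= 1", arg), call. = FALSE)
  }
  if (!all(is.finite(f))) {
    stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  }
  invisible(f)
}

# Lift a (C,H,W) map to a (1,C,H,W) batch and back.
as_batch <- function(f) {
  d <- dim(f)
  array(f, dim = c(1L, d))
}

from_batch <- function(x) {
  d <- dim(x)
  stopifnot(d[1] == 1L)
  array(x, dim = d[-1])
}

# Row-wise max and argmax of a matrix, vectorised over columns (fast when the
# number of columns is small, which is always the case for channel counts).
row_max_idx <- function(m) {
  n <- nrow(m)
  best <- m[, 1L]
  idx <- rep.int(1L, n)
  nc <- ncol(m)
  if (nc > 1L) {
    for (j in 2L:nc) {
      upd <- m[, j] > best
      best[upd] <- m[upd, j]
      idx[upd] <- j
    }
  }
  list(max = best, idx = idx)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-channel moments of an (N,C,H,W) batch, taken over (N,H,W).
channel_moments <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(2L, 1L, 3L, 4L))
  dim(xp) <- c(d[2], d[1] * d[3] * d[4])
  mu <- rowMeans(xp)
  v <- rowMeans(xp * xp) - mu * mu
  list(mean = mu, var = pmax(v, 0))
}

# Multiply an (N,C,H,W) batch by a per-(n,c) matrix (broadcast over space).
scale_nc <- function(x, s) {
  x * as.vector(s)
}

# Sum an (N,C,H,W) batch over space, returning an (N,C) matrix.
sum_spatial <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- rowSums(xm)
  dim(out) <- d[1:2]
  out
}
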