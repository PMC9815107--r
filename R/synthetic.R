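# Seeded generator of cassava-like leaf images: a textured leaf-green
# background carrying class-specific lesion motifs. The five default classes
# mirror the cassava disease vocabulary -- bacterial blight (pale angular
# blotches), brown streak disease (elongated brown streaks), green mottle
# (green-on-green dots), mosaic disease (yellow patches) and healthy leaves
# (no lesions). Motif colours and counts separate the classes by colour
# statistics alone, which is what makes tiny smoke-training runs converge.

#' Default synthetic class specification
#'
#' One entry per class: motif type, per-image motif count range, motif colour
#' (RGB, 0..255), and relative motif size range (fraction of the shorter
#' image side). `noise_sd` is the additive pixel noise, `base_rgb` the leaf
#' background colour.
#'
#' @return Named list usable as `class_spec` in
#'   [generate_synthetic_dataset()].
#' @export
default_class_spec <- function() {
  list(
    cbb = list(motif = "blotch", count = c(4L, 9L),
               color = c(205, 200, 150), size = c(0.06, 0.16)),
    cbsd = list(motif = "streak", count = c(5L, 11L),
                color = c(110, 70, 30), size = c(0.15, 0.45)),
    cgm = list(motif = "dot", count = c(35L, 80L),
               color = c(95, 160, 60), size = c(0.01, 0.035)),
    cmd = list(motif = "patch", count = c(6L, 12L),
               color = c(190, 185, 45), size = c(0.05, 0.14)),
    healthy = list(motif = "none", count = c(0L, 0L),
                   color = c(0, 0, 0), size = c(0, 0)),
    base_rgb = c(62, 112, 48),
    noise_sd = 8
  )
}

# Smooth low-frequency field in [-1, 1] built from a few random cosine waves.
smooth_field <- function(h, w, n_waves = 3L) {
  ih <- seq_len(h) / h
  iw <- seq_len(w) / w
  f <- matrix(0, h, w)
  for (k in seq_len(n_waves)) {
    fh <- stats::runif(1, 0.5, 2.5)
    fw <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(1, 0, 2 * pi)
    pw <- stats::runif(1, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * fh * ih + ph), cos(2 * pi * fw * iw + pw))
  }
  f / n_waves
}

stamp_disc <- function(img, cy, cx, radius, rgb, alpha = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- ceiling(radius)
  if (cy + r < 1 || cy - r > h || cx + r < 1 || cx - r > w) return(img)
  ys <- max(1, cy - r):min(h, cy + r)
  xs <- max(1, cx - r):min(w, cx + r)
  mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
  for (ch in 1:3) {
    sl <- img[ys, xs, ch]
    sl[mask] <- (1 - alpha) * sl[mask] + alpha * rgb[ch]
    img[ys, xs, ch] <- sl
  }
  img
}

stamp_streak <- function(img, y0, x0, y1, x1, thickness, rgb, alpha = 1) {
  len <- max(abs(y1 - y0), abs(x1 - x0), 1)
  ts <- seq(0, 1, length.out = 2L * len)
  for (t in ts) {
    img <- stamp_disc(img, round(y0 + t * (y1 - y0)),
                      round(x0 + t * (x1 - x0)), thickness, rgb, alpha)
  }
  img
}

render_synthetic_image <- function(h, w, cls, spec) {
  base <- spec$base_rgb + stats::runif(3, -12, 12)
  img <- array(0, c(h, w, 3L))
  field <- smooth_field(h, w)
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + 18 * field +
      stats::rnorm(h * w, sd = spec$noise_sd)
  }
  cs <- spec[[cls]]
  if (cs$motif != "none") {
    n_motif <- sample(cs$count[1]:cs$count[2], 1L)
    short <- min(h, w)
    for (i in seq_len(n_motif)) {
      size <- stats::runif(1, cs$size[1], cs$size[2]) * short
      cy <- sample.int(h, 1L)
      cx <- sample.int(w, 1L)
      col <- cs$color + stats::runif(3, -15, 15)
      if (cs$motif == "dot") {
        img <- stamp_disc(img, cy, cx, max(1, size), col, alpha = 0.9)
      } else if (cs$motif == "blotch" || cs$motif == "patch") {
        # irregular blotch: a cluster of overlapping discs
        for (j in 1:4) {
          img <- stamp_disc(img, cy + round(stats::runif(1, -size, size) / 2),
                            cx + round(stats::runif(1, -size, size) / 2),
                            max(1, size / 2), col, alpha = 0.85)
        }
      } else if (cs$motif == "streak") {
        ang <- stats::runif(1, 0, pi)
        dy <- round(sin(ang) * size)
        dx <- round(cos(ang) * size)
        img <- stamp_streak(img, cy - dy, cx - dx, cy + dy, cx + dx,
                            max(1, 0.02 * short), col, alpha = 0.9)
      }
    }
  }
  round(pmin(pmax(img, 0), 255))
}

#' Generate a synthetic cassava-like image dataset
#'
#' Renders `n_per_class` images per class into `out_dir/<class>/` as PNG
#' files and returns the matching manifest. Generation is deterministic given
#' `seed` (identical bytes on re-run). Class imbalance is configurable by
#' giving `n_per_class` as a named-or-positional vector with one count per
#' class.
#'
#' @param out_dir Directory to materialize the image folder into.
#' @param n_per_class Images per class: a single count or one per class.
#' @param image_size `(H, W)` in pixels; default 600 x 800, the shape of the
#'   field photographs the generator emulates.
#' @param class_spec Motif specification, see [default_class_spec()].
#' @param seed Integer seed.
#' @return An `msf_manifest` of the generated images.
#' @export
generate_synthetic_dataset <- function(out_dir, n_per_class = 100L,
                                       image_size = c(600L, 800L),
                                       class_spec = default_class_spec(),
                                       seed = 1L) {
  if (any(n_per_class < 1L)) stop("n_per_class must be >= 1", call. = FALSE)
  classes <- setdiff(names(class_spec), c("base_rgb", "noise_sd"))
  if (length(n_per_class) == 1L) {
    n_per_class <- rep(as.integer(n_per_class), length(classes))
  }
  stopifnot(length(n_per_class) == length(classes))
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- with_seed(seed, {
    acc <- list()
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      cls_dir <- file.path(out_dir, cl)
      dir.create(cls_dir, showWarnings = FALSE)
      for (i in seq_len(n_per_class[ci])) {
        img <- render_synthetic_image(h, w, cl, class_spec)
        fp <- file.path(cls_dir, sprintf("%s_%04d.png", cl, i))
        write_image(img, fp)
        acc[[length(acc) + 1L]] <-
          data.frame(path = fp, label = cl, provenance = "original")
      }
    }
    acc
  })
  new_manifest(do.call(rbind, rows), sort(classes))
}
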