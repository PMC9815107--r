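# Offline augmentation recipe: 180-degree rotation, brightness scaling to
# 70%, horizontal flip. Variants are emitted next to the originals with
# provenance tags, either materialized to disk or as lazy manifest records
# whose transform is applied on read.

validate_image <- function(img, arg = "img") {
  if (!is.numeric(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 numeric array", arg),
         call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` values must lie in [0, 255]", arg), call. = FALSE)
  }
  invisible(img)
}

#' Rotate an image by 180 degrees
#'
#' Pixel (i, j) maps to (H - 1 - i, W - 1 - j); applying the operation twice
#' returns the original image exactly.
#'
#' @param img H x W x 3 array with values in 0..255.
#' @return Array of the same shape.
#' @export
rotate180 <- function(img) {
  validate_image(img)
  img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Flip an image horizontally
#'
#' Column j maps to W - 1 - j (mirror about the vertical axis); an involution.
#'
#' @inheritParams rotate180
#' @return Array of the same shape.
#' @export
hflip <- function(img) {
  validate_image(img)
  img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Scale image brightness
#'
#' Multiplies every channel by `factor`, rounds half away from zero and clips
#' to 0..255. `factor = 0.7` reproduces the reference augmentation recipe
#' (brightness becomes 70% of the original); `factor = 1` is the identity.
#'
#' @inheritParams rotate180
#' @param factor Positive brightness factor.
#' @return Array of the same shape, integer-valued in 0..255.
#' @export
adjust_brightness <- function(img, factor) {
  validate_image(img)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a positive number", call. = FALSE)
  }
  out <- floor(img * factor + 0.5)   # round half away from zero (values >= 0)
  out[out > 255] <- 255
  dim(out) <- dim(img)
  out
}

#' Augmentation recipe specification
#'
#' @param brightness Brightness-reduction factor (default 0.7).
#' @param include_increase Also emit a brightness-increase variant (default
#'   `FALSE`; the reference recipe only decreases).
#' @param increase Brightness-increase factor used when enabled.
#' @param per_class_cap Optional cap on the total records per class after
#'   augmentation; variants are truncated in deterministic order (all
#'   originals, then all rotations, then all brightness variants, then all
#'   flips).
#' @return An `augment_spec` object.
#' @export
augment_spec <- function(brightness = 0.7, include_increase = FALSE,
                         increase = 1.3, per_class_cap = NULL) {
  structure(list(brightness = brightness,
                 include_increase = isTRUE(include_increase),
                 increase = increase, per_class_cap = per_class_cap),
            class = "augment_spec")
}

#' Augment a dataset manifest
#'
#' Emits the original records plus, per image, a 180-degree rotation, a
#' brightness-scaled copy and a horizontal flip, each carrying a provenance
#' tag. With `out_dir` the variants are materialized as PNG files (offline
#' augmentation); without it the manifest records are lazy and the transform
#' is applied when the image is read.
#'
#' @param manifest An `msf_manifest` of original records.
#' @param spec An [augment_spec()].
#' @param out_dir Optional directory in which to materialize variant images.
#' @return An `msf_manifest` containing originals and variants; labels of
#'   variants equal their source labels.
#' @export
augment_dataset <- function(manifest, spec = augment_spec(), out_dir = NULL) {
  stopifnot(inherits(manifest, "msf_manifest"))
  df <- as.data.frame(manifest)
  variants <- c("rotate180", paste0("brightness", spec$brightness), "hflip")
  if (spec$include_increase) {
    variants <- c(variants, paste0("brightness", spec$increase))
  }
  pieces <- list(df)
  for (v in variants) {
    vd <- df
    vd$provenance <- v
    pieces[[length(pieces) + 1L]] <- vd
  }
  out <- do.call(rbind, pieces)
  # deterministic order within class: originals first, then variant blocks
  out <- out[order(match(out$label, attr(manifest, "classes")),
                   match(out$provenance, c("original", variants)),
                   out$path), ]
  if (!is.null(spec$per_class_cap)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$label), function(ix) {
      ix[seq_len(min(length(ix), spec$per_class_cap))]
    }), use.names = FALSE)
    out <- out[sort(keep), ]
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(out))) {
      if (out$provenance[i] == "original") next
      src <- out$path[i]
      img <- apply_provenance(read_image(src), out$provenance[i])
      cls_dir <- file.path(out_dir, out$label[i])
      dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
      new_path <- file.path(cls_dir, paste0(
        tools::file_path_sans_ext(basename(src)), "_", out$provenance[i],
        ".png"))
      write_image(img, new_path)
      out$path[i] <- new_path
    }
  }
  new_manifest(out, attr(manifest, "classes"), attr(manifest, "excluded"))
}
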