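# Dataset ingestion. Images are H x W x 3 arrays of 8-bit intensities
# (0..255, RGB order). A dataset manifest is a data.frame with columns
# path, label, provenance and a "classes" attribute holding the ordered
# label vocabulary; manifests are the unit the splitter, augmenter and
# training loop all operate on.

new_manifest <- function(df, classes, excluded = NULL) {
  rownames(df) <- NULL
  structure(df, classes = classes,
            excluded = if (is.null(excluded)) {
              data.frame(path = character(0), reason = character(0))
            } else excluded,
            class = c("msf_manifest", "data.frame"))
}

#' @export
print.msf_manifest <- function(x, ...) {
  cl <- attr(x, "classes")
  cat(sprintf("msf_manifest: %d records, %d classes (%s)\n",
              nrow(x), length(cl), paste(cl, collapse = ", ")))
  excl <- attr(x, "excluded")
  if (!is.null(excl) && nrow(excl) > 0) {
    cat(sprintf("  %d file(s) excluded as unreadable\n", nrow(excl)))
  }
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Class vocabulary of a manifest
#' @param manifest An `msf_manifest`.
#' @return Character vector of ordered class labels.
#' @export
manifest_classes <- function(manifest) attr(manifest, "classes")

#' Files excluded while scanning a folder
#' @param manifest An `msf_manifest` from [load_image_folder()].
#' @return data.frame with columns `path` and `reason`.
#' @export
manifest_exclusions <- function(manifest) attr(manifest, "excluded")

#' Read an image file into an 8-bit RGB array
#'
#' PNG files are read with the png package; JPEG files through EBImage when
#' that package is installed. Grayscale and alpha channels are expanded or
#' dropped to a plain H x W x 3 array of integers in 0..255.
#'
#' @param path Image file path.
#' @return Numeric H x W x 3 array with values in 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG input requires the EBImage package", call. = FALSE)
    }
    img <- EBImage::imageData(EBImage::readImage(path))
    img <- aperm(img, c(2L, 1L, 3L)[seq_along(dim(img))])
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB array as PNG
#' @param img Numeric H x W x 3 array with values in 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Scan a directory-per-class image folder into a manifest
#'
#' Each subdirectory of `root` is one class; its PNG/JPEG files become
#' records labelled with the directory name. Scanning is deterministic:
#' classes and files are taken in lexicographic order. Unreadable files are
#' not silently dropped -- they are listed in the exclusion report available
#' via [manifest_exclusions()], and empty class directories raise a warning.
#'
#' @param root Path to the dataset root.
#' @param validate Verify that every file actually decodes (default `TRUE`).
#' @return An `msf_manifest` with columns `path`, `label`, `provenance`.
#' @export
load_image_folder <- function(root, validate = TRUE) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) {
    stop("`root` must contain one subdirectory per class", call. = FALSE)
  }
  rows <- list()
  excluded <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) {
      warning("empty class directory: ", cl, call. = FALSE)
      next
    }
    for (fp in files) {
      ok <- TRUE
      reason <- NA_character_
      if (validate) {
        ok <- tryCatch({read_image(fp); TRUE},
                       error = function(e) {reason <<- conditionMessage(e); FALSE})
      }
      if (ok) {
        rows[[length(rows) + 1L]] <-
          data.frame(path = fp, label = cl, provenance = "original")
      } else {
        excluded[[length(excluded) + 1L]] <-
          data.frame(path = fp, reason = reason)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), label = character(0),
               provenance = character(0))
  excl <- if (length(excluded)) do.call(rbind, excluded) else NULL
  new_manifest(df, classes, excl)
}

# Read a manifest record, applying its provenance transform when the record
# is a lazy augmentation variant.
load_record_image <- function(path, provenance = "original") {
  img <- read_image(path)
  apply_provenance(img, provenance)
}

apply_provenance <- function(img, provenance) {
  if (provenance == "original") return(img)
  if (provenance == "rotate180") return(rotate180(img))
  if (provenance == "hflip") return(hflip(img))
  if (startsWith(provenance, "brightness")) {
    fac <- as.numeric(sub("^brightness", "", provenance))
    return(adjust_brightness(img, fac))
  }
  stop("unknown provenance tag: ", provenance, call. = FALSE)
}
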