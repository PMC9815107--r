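# Stratified dataset splitting with largest-remainder apportionment, so the
# split sizes are the exact integer apportionment of the requested ratios
# (per class when stratified) and every record lands in exactly one split.

#' Split ratio specification
#'
#' @param ratios Nonnegative (train, val, test) proportions summing to 1
#'   within 1e-9. The default 8:1:1 follows the training protocol; the 90/10
#'   preset `split_spec(c(0.9, 0, 0.1))` matches the plain train/test
#'   division.
#' @param seed Integer seed for the random assignment.
#' @param stratified Apportion per class (default `TRUE`) or over the pooled
#'   manifest.
#' @return A `split_spec` object.
#' @export
split_spec <- function(ratios = c(0.8, 0.1, 0.1), seed = 1L,
                       stratified = TRUE) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three nonnegative numbers summing to 1",
         call. = FALSE)
  }
  structure(list(ratios = ratios, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to ratios;
# ties broken in favour of earlier parts (train before val before test).
apportion <- function(n, ratios) {
  q <- n * ratios
  f <- floor(q)
  rem <- n - sum(f)
  if (rem > 0) {
    ord <- order(q - f, decreasing = TRUE)  # stable: earlier split wins ties
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

#' Split a manifest into train / validation / test
#'
#' Record counts per split follow largest-remainder apportionment of the
#' ratios (applied within each class when stratified), assignment is a seeded
#' permutation, and the three parts are disjoint with union equal to the
#' input manifest.
#'
#' @param manifest An `msf_manifest`.
#' @param spec A [split_spec()].
#' @return Named list of manifests `train`, `val`, `test`, each carrying a
#'   `split` column.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(manifest, "msf_manifest"), inherits(spec, "split_spec"))
  df <- as.data.frame(manifest)
  n <- nrow(df)
  assign_split <- function(idx) {
    counts <- apportion(length(idx), spec$ratios)
    lab <- rep(c("train", "val", "test"), counts)
    data.frame(idx = idx[sample.int(length(idx))], split = lab)
  }
  assignment <- with_seed(spec$seed, {
    if (spec$stratified) {
      parts <- split(seq_len(n), df$label)
      do.call(rbind, lapply(parts, assign_split))
    } else {
      assign_split(seq_len(n))
    }
  })
  split_of <- character(n)
  split_of[assignment$idx] <- assignment$split
  df$split <- split_of
  classes <- attr(manifest, "classes")
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    new_manifest(df[df$split == s, , drop = FALSE], classes)
  })
  out
}

#' Write a manifest as CSV
#'
#' Columns: path, label, split (when present), provenance.
#'
#' @param manifest An `msf_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  if (!"split" %in% names(df)) df$split <- NA_character_
  utils::write.csv(df[, c("path", "label", "split", "provenance")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a manifest CSV written by [write_manifest()]
#'
#' @param path CSV path.
#' @param classes Optional class vocabulary; defaults to the sorted labels
#'   present.
#' @return An `msf_manifest`.
#' @export
read_manifest <- function(path, classes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(classes)) classes <- sort(unique(df$label))
  new_manifest(df, classes)
}
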