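# Confusion-matrix evaluation. Convention, fixed in every output: rows are
# the true class, columns the predicted class, so row sums are the per-class
# sample counts and the trace over the total is the overall accuracy.

#' Build a confusion matrix
#'
#' `counts[i, j]` is the number of samples whose true class is `i` and whose
#' predicted class is `j` (rows = truth, columns = prediction).
#'
#' @param truth,pred Equal-length vectors of 1-based class indices (or
#'   factors/characters over `labels`).
#' @param n_classes Number of classes K; inferred from `labels` when given.
#' @param labels Optional character vector of class names.
#' @return An `msf_confusion` object holding the K x K count matrix.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL, labels = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (!is.null(labels)) n_classes <- length(labels)
  to_idx <- function(v) {
    if (is.factor(v)) v <- as.character(v)
    if (is.character(v)) {
      if (is.null(labels)) stop("labels required for character input",
                                call. = FALSE)
      v <- match(v, labels)
    }
    as.integer(v)
  }
  ti <- to_idx(truth); pi <- to_idx(pred)
  if (is.null(n_classes)) n_classes <- max(ti, pi)
  if (anyNA(ti) || anyNA(pi) || any(ti < 1L) || any(pi < 1L) ||
      any(ti > n_classes) || any(pi > n_classes)) {
    stop("labels out of range 1..K", call. = FALSE)
  }
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(ti)) {
    counts[ti[i], pi[i]] <- counts[ti[i], pi[i]] + 1L
  }
  if (is.null(labels)) labels <- paste0("class", seq_len(n_classes))
  dimnames(counts) <- list(truth = labels, predicted = labels)
  structure(list(counts = counts, labels = labels), class = "msf_confusion")
}

#' @export
print.msf_confusion <- function(x, ...) {
  cat("confusion matrix (rows = true class, columns = predicted class)\n")
  print(x$counts)
  invisible(x)
}

#' Per-class and overall metrics of a confusion matrix
#'
#' For each class c (one-vs-rest): precision = TP / (TP + FP), recall =
#' TP / (TP + FN), accuracy = (TP + TN) / total. Overall accuracy is the
#' trace over the total. Degenerate denominators yield 0 with the `flagged`
#' column set, never NaN. Micro-averaged precision and recall are also
#' reported; in single-label multiclass both equal the overall accuracy.
#'
#' @param cm An `msf_confusion`.
#' @return List with `per_class` (data.frame class/tp/fp/fn/tn/precision/
#'   recall/accuracy/flagged), `accuracy`, and `micro`
#'   (list of precision, recall).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "msf_confusion"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- data.frame(
    class = cm$labels,
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    accuracy = (tp + tn) / total,
    flagged = (tp + fp) == 0 | (tp + fn) == 0)
  rownames(per_class) <- NULL
  list(per_class = per_class,
       accuracy = sum(tp) / total,
       micro = list(precision = sum(tp) / sum(tp + fp),
                    recall = sum(tp) / sum(tp + fn)))
}

#' Export a confusion matrix / classification report as CSV
#'
#' @param cm An `msf_confusion`.
#' @param path Output CSV path.
#' @param normalize Divide each row by its row sum (per-class rates).
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path, normalize = FALSE) {
  m <- cm$counts
  if (normalize) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  df <- as.data.frame(m)
  df <- cbind(true_class = cm$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
write_classification_report <- function(cm, path) {
  met <- confusion_metrics(cm)
  df <- met$per_class[, c("class", "precision", "recall", "accuracy")]
  df <- rbind(df, data.frame(class = "overall", precision = met$micro$precision,
                             recall = met$micro$recall,
                             accuracy = met$accuracy))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a confusion matrix as a figure
#'
#' Draws the count (or row-normalized) matrix as a shaded grid with the cell
#' values printed, rows = truth and columns = prediction.
#'
#' @param cm An `msf_confusion`.
#' @param file Optional PNG path; `NULL` draws on the active device.
#' @param normalize Show per-class rates instead of raw counts.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_confusion <- function(cm, file = NULL, normalize = FALSE) {
  m <- cm$counts
  if (normalize) {
    rs <- rowSums(m); rs[rs == 0] <- 1
    m <- m / rs
  }
  k <- nrow(m)
  if (!is.null(file)) grDevices::png(file, width = 640, height = 600)
  op <- graphics::par(mar = c(5, 6, 3, 1))
  on.exit({graphics::par(op); if (!is.null(file)) grDevices::dev.off()})
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted class", ylab = "",
                  main = if (normalize) "confusion matrix (row-normalized)"
                         else "confusion matrix (counts)")
  graphics::axis(1, at = seq_len(k), labels = cm$labels, las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(cm$labels), las = 1)
  graphics::mtext("true class", side = 2, line = 4.5)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    val <- m[i, j]
    graphics::text(j, k - i + 1,
                   if (normalize) sprintf("%.2f", val) else as.character(val),
                   col = if (val > max(m) / 2) "white" else "black")
  }
  invisible(file)
}
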