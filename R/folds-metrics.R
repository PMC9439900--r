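# Stratified k-fold assignment and the evaluation metric suite.

#' Stratified k-fold assignment
#'
#' Assigns each labeled sample to exactly one of `k` folds, stratified so
#' that per-class fold sizes differ by at most one. Deterministic for a
#' fixed seed.
#'
#' @param labels A data frame (or tibble) with columns `sample_id` and
#'   `class`, or a named character vector of classes.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `fold_plan` tibble with columns `sample_id`, `class`, `fold`
#'   (integer in `0:(k-1)`), and attributes `k` and `seed`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(sample_id = names(labels), class = unname(labels))
  }
  if (!all(c("sample_id", "class") %in% names(labels))) {
    abort("`labels` needs columns `sample_id` and `class`.")
  }
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.")
  counts <- table(labels$class)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    abort(sprintf("class %s has fewer than k = %d samples.",
                  paste(shQuote(small), collapse = ", "), k))
  }
  out <- with_seed(seed, {
    dplyr::bind_rows(lapply(split(labels, labels$class), function(g) {
      ord <- sample.int(nrow(g))
      folds <- sort(rep_len(0:(k - 1L), nrow(g)))
      g$fold <- NA_integer_
      g$fold[ord] <- folds
      g
    }))
  })
  out <- out[match(labels$sample_id, out$sample_id), ]
  out <- tibble::as_tibble(out)
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("fold_plan", class(out))
  out
}

#' Classification metrics from predictions and truth
#'
#' Computes per-class confusion counts (TP, FP, TN, FN) and the derived
#' accuracy, precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 = 2 PR / (P + R), averaged across classes either by class support
#' (`"weighted"`) or unweighted (`"macro"`). A precision or recall whose
#' denominator is zero is defined as 0, with a warning. In a binary task,
#' support-weighted recall equals overall accuracy exactly.
#'
#' @param pred Vector of predicted class labels.
#' @param truth Vector of true class labels (same length).
#' @param averaging `"weighted"` (default) or `"macro"`.
#' @param classes Optional explicit class set (defaults to the union of the
#'   labels observed in `truth` and `pred`, sorted).
#' @return A `metrics_report` list with `accuracy`, `precision`, `recall`,
#'   `f1`, `averaging`, and a `per_class` tibble of counts and metrics.
#' @export
compute_metrics <- function(pred, truth, averaging = c("weighted", "macro"),
                            classes = NULL) {
  averaging <- match.arg(averaging)
  if (length(pred) != length(truth)) {
    abort(sprintf("`pred` (%d) and `truth` (%d) differ in length.",
                  length(pred), length(truth)))
  }
  if (length(truth) == 0L) abort("no samples to evaluate.")
  pred <- as.character(pred); truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  n <- length(truth)
  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0L) {
      warn(sprintf("class '%s' was never predicted; precision defined as 0.", cl))
      0
    } else tp / (tp + fp)
    rec <- if (tp + fn == 0L) {
      warn(sprintf("class '%s' has no true samples; recall defined as 0.", cl))
      0
    } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
                   support = tp + fn, precision = prec, recall = rec, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  if (averaging == "weighted") {
    # support-weighted: recall is computed as sum(TP)/n, which makes the
    # binary identity weighted-recall == accuracy exact (not just to rounding)
    avg_precision <- sum(per$support * per$precision) / n
    avg_recall <- sum(per$tp) / n
    avg_f1 <- sum(per$support * per$f1) / n
  } else {
    avg_precision <- mean(per$precision)
    avg_recall <- mean(per$recall)
    avg_f1 <- mean(per$f1)
  }
  structure(
    list(
      accuracy = sum(pred == truth) / n,
      precision = avg_precision,
      recall = avg_recall,
      f1 = avg_f1,
      averaging = averaging,
      n = n,
      per_class = per
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d, %s averaging\n  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
    x$n, x$averaging, x$accuracy, x$precision, x$recall, x$f1))
  print(x$per_class)
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, averaging = x$averaging,
                 n = x$n)
}
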