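#' Confusion counts for binary predictions
#'
#' Counts follow the usual case-control layout: `a` true positives,
#' `b` false negatives, `c` false positives, `d` true negatives, so that
#' `a + b` is the number of actual cases and `c + d` the number of actual
#' controls.
#'
#' @param pred Predicted 0/1 labels.
#' @param truth True 0/1 labels, same length.
#' @return A `confusion_matrix` list with fields `a`, `b`, `c`, `d`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("pred and truth differ in length")
  }
  pred <- as.integer(pred); truth <- as.integer(truth)
  structure(list(
    a = sum(pred == 1L & truth == 1L),
    b = sum(pred == 0L & truth == 1L),
    c = sum(pred == 1L & truth == 0L),
    d = sum(pred == 0L & truth == 0L)
  ), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#' @param a,b,c,d True positives, false negatives, false positives, true
#'   negatives.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("confusion counts must be >= 0")
  structure(list(a = a, b = b, c = c, d = d), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("# confusion: a=%d (TP) b=%d (FN) c=%d (FP) d=%d (TN)\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Precision, recall, accuracy and F1 from confusion counts
#'
#' Precision p = a/(a+c), recall r = a/(a+b), accuracy = (a+d)/(a+b+c+d),
#' F1 = 2pr/(p+r) = 2a/(2a+b+c). A metric whose denominator is zero is
#' reported as 0 and flagged in `degenerate` rather than raising, so
#' cross-validation sweeps survive degenerate folds.
#'
#' @param cm A `confusion_matrix`.
#' @return A tibble with columns `precision`, `recall`, `accuracy`, `f1`,
#'   and `degenerate` (comma-separated names of zero-denominator metrics,
#'   `""` if none).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  a <- cm$a; b <- cm$b; c <- cm$c; d <- cm$d
  flags <- character(0)
  prec <- if (a + c > 0) a / (a + c) else { flags <- c(flags, "precision"); 0 }
  rec <- if (a + b > 0) a / (a + b) else { flags <- c(flags, "recall"); 0 }
  acc <- if (a + b + c + d > 0) (a + d) / (a + b + c + d) else {
    flags <- c(flags, "accuracy"); 0
  }
  f1 <- if (2 * a + b + c > 0) 2 * a / (2 * a + b + c) else {
    flags <- c(flags, "f1"); 0
  }
  tibble(precision = prec, recall = rec, accuracy = acc, f1 = f1,
         degenerate = paste(flags, collapse = ","))
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique predicted probabilities in
#' descending order (a sample is called positive when its probability is >=
#' the threshold), yielding one (FPR, TPR) point per threshold; sentinel
#' points anchor the curve at (0, 0) and (1, 1). Tied probabilities
#' collapse into a single point.
#'
#' @param probabilities Finite case-probability vector.
#' @param truth 0/1 labels with both classes present.
#' @return A `roc_curve` tibble: `threshold`, `fpr`, `tpr`. The sentinels
#'   carry thresholds `Inf` and `-Inf`.
#' @export
roc_curve <- function(probabilities, truth) {
  if (!all(is.finite(probabilities))) abort("probabilities must be finite")
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC requires both classes in truth")
  }
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probabilities >= t & truth == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(probabilities >= t & truth == 0L) / n_neg,
                numeric(1))
  structure(
    tibble(threshold = c(Inf, thr, -Inf),
           fpr = c(0, fpr, 1),
           tpr = c(0, tpr, 1)),
    class = c("roc_curve", class(tibble()))
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area of the exact step curve over FPR (no interpolation
#' smoothing). Equals the probability that a random case receives a higher
#' probability than a random control (ties counted half).
#'
#' @param curve A `roc_curve` from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC curve (AUC = %.3f)", auc(object))) +
    theme_minimal()
}

#' Evaluate predictions on a held-out test set
#'
#' Assembles the full report for one train/test experiment: confusion
#' counts, the four derived metrics, the ROC sweep and its AUC, plus the
#' configuration provenance that produced the predictions.
#'
#' @param probabilities Case probabilities on the test samples.
#' @param truth True 0/1 labels.
#' @param p_t Decision threshold applied (default 0.5).
#' @param provenance Optional named list recording how the predictions were
#'   produced (selection, model spec, seeds).
#' @return An `evaluation_report` list: `confusion`, `metrics` (tibble),
#'   `roc` (`roc_curve`), `auc`, `p_t`, `provenance`.
#' @export
evaluate_predictions <- function(probabilities, truth, p_t = 0.5,
                                 provenance = list()) {
  if (is.data.frame(truth)) truth <- truth$label
  cm <- confusion(classify(probabilities, p_t), truth)
  roc <- roc_curve(probabilities, truth)
  structure(list(confusion = cm,
                 metrics = classification_metrics(cm),
                 roc = roc, auc = auc(roc), p_t = p_t,
                 provenance = provenance),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "# evaluation_report (p_t = %.2f)\n",
    "#   a=%d b=%d c=%d d=%d\n",
    "#   F1 %.4f | accuracy %.4f | precision %.4f | recall %.4f | AUC %.4f\n"),
    x$p_t, x$confusion$a, x$confusion$b, x$confusion$c, x$confusion$d,
    m$f1, m$accuracy, m$precision, m$recall, x$auc))
  invisible(x)
}

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(a = x$confusion$a, b = x$confusion$b,
           c = x$confusion$c, d = x$confusion$d),
    x$metrics[, c("precision", "recall", "accuracy", "f1")],
    tibble(auc = x$auc, p_t = x$p_t)
  )
}

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) tidy(x)

#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) autoplot(object$roc, ...)

#' Write an evaluation report to disk
#'
#' Emits a flat key-value text file of the counts and metrics plus a
#' two-column TSV of ROC points.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return Named vector of written paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kv_path <- file.path(dir, "report.txt")
  roc_path <- file.path(dir, "roc.tsv")
  t <- tidy(report)
  writeLines(paste(names(t), unlist(t), sep = "\t"), kv_path)
  utils::write.table(as.data.frame(report$roc), roc_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(report = kv_path, roc = roc_path)
}
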