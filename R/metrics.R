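# Evaluation panel for screening classifiers: recall, precision, F-score,
# ROC area and accuracy, with the active class as positive. ROC area is
# computed from ranking scores (the forest's vote fractions) by the
# Mann-Whitney identity: the probability that a uniformly random active
# compound scores above a uniformly random inactive one, ties counted 1/2.

.as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    v <- tolower(trimws(y))
    out <- ifelse(v %in% c("active", "1", "true"), 1L,
                  ifelse(v %in% c("inactive", "0", "false"), 0L, NA_integer_))
    if (anyNA(out)) stop("unmappable labels: ",
                         paste(unique(y[is.na(out)]), collapse = ", "))
    return(out)
  }
  out <- as.integer(y)
  if (anyNA(out) || !all(out %in% c(0L, 1L))) stop("labels must be binary 0/1")
  out
}

#' Confusion counts with active as the positive class
#'
#' @param y_true,y_pred equal-length binary label vectors (0/1, logical, or
#'   "active"/"inactive" strings).
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("cannot build a confusion matrix from no data")
  if (length(y_true) != length(y_pred)) {
    stop("y_true (", length(y_true), ") and y_pred (", length(y_pred),
         ") differ in length")
  }
  yt <- .as_binary_label(y_true)
  yp <- .as_binary_label(y_pred)
  structure(list(
    tp = sum(yt == 1L & yp == 1L),
    fp = sum(yt == 0L & yp == 1L),
    tn = sum(yt == 0L & yp == 0L),
    fn = sum(yt == 1L & yp == 0L)
  ), class = "confusion_counts")
}

#' ROC area from ranking scores
#'
#' Mann-Whitney formulation: `P(score_active > score_inactive)`, ties
#' counted one half, computed from rank sums.
#'
#' @param scores numeric ranking values (higher = more active-like).
#' @param y_true binary labels.
#' @return area in `[0, 1]`, or `NA` (with a warning) when a class is absent.
#' @export
roc_area <- function(scores, y_true) {
  yt <- .as_binary_label(y_true)
  if (length(scores) != length(yt)) {
    stop("scores (", length(scores), ") and labels (", length(yt),
         ") differ in length")
  }
  n1 <- sum(yt == 1L); n0 <- sum(yt == 0L)
  if (n1 == 0 || n0 == 0) {
    warning("ROC area undefined: one class absent", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[yt == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compute the screening metric panel
#'
#' recall = tp/(tp+fn), precision = tp/(tp+fp), accuracy = (tp+tn)/total,
#' F-score = harmonic mean of precision and recall, and (when scores are
#' supplied) the Mann-Whitney ROC area. Ratios with a zero denominator are
#' reported as `NA` with a warning -- never silently as 0, so degenerate
#' predictions stay visible.
#'
#' @param counts a [confusion()] result.
#' @param scores optional per-compound ranking values for the ROC area.
#' @param y_true labels matching `scores` (required with `scores`).
#' @return object of class `metrics_report` with fields `recall`,
#'   `precision`, `f_score`, `roc_area`, `accuracy`, `n`, `n_active`.
#' @export
compute_metrics <- function(counts, scores = NULL, y_true = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      NA_real_
    } else num / den
  }
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn, "recall")
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  accuracy <- safe_ratio(counts$tp + counts$tn, total, "accuracy")
  f_score <- if (is.na(recall) || is.na(precision)) {
    NA_real_
  } else if (recall + precision == 0) {
    warning("F-score undefined (precision + recall = 0)", call. = FALSE)
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true is required to compute the ROC area")
    auc <- roc_area(scores, y_true)
  }
  structure(list(recall = recall, precision = precision, f_score = f_score,
                 roc_area = auc, accuracy = accuracy, n = total,
                 n_active = counts$tp + counts$fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "   NA" else sprintf("%.*f", digits, v)
  cat("Recall  Precision  F-score  ROC area  Accuracy\n")
  cat(sprintf("%-7s %-10s %-8s %-9s %-8s\n", fmt(x$recall), fmt(x$precision),
              fmt(x$f_score), fmt(x$roc_area), fmt(x$accuracy)))
  cat(sprintf("(n = %d, actives = %d)\n", x$n, x$n_active))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(recall = report$recall, precision = report$precision,
         f_score = report$f_score, roc_area = report$roc_area,
         accuracy = report$accuracy, n = report$n,
         n_active = report$n_active),
    path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' Evaluate a forest on a labelled feature table
#'
#' Predicts with [predict_forest()], uses the vote fractions as ranking
#' scores, and returns the full metric panel.
#'
#' @param model a `forest_model`.
#' @param table labelled [feature_table()].
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("evaluation requires a labelled table")
  pr <- predict_forest(model, table)
  compute_metrics(confusion(table$labels, pr$labels),
                  scores = pr$votes$score, y_true = table$labels)
}
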