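# Classification metrics: confusion counts, accuracy/precision/recall/F1,
# ROC and precision-recall curves with areas, the one-vs-rest multiclass
# extension with class-averaged overall scores, and cross-tabulation of two
# label sets.

#' Binary confusion counts
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return named vector (TP, FP, FN, TN).
#' @export
binary_counts <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  c(TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0),
    TN = sum(y_true == 0 & y_pred == 0))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Precision, recall and F1 are defined as 0 when their denominator is 0.
#'
#' @param counts named vector with TP, FP, FN, TN.
#' @return named vector (accuracy, precision, recall, F1).
#' @export
accuracy_f1 <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  n <- tp + fp + fn + tn
  if (n == 0) stop("no observations")
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = (tp + tn) / n, precision = prec, recall = rec, F1 = f1)
}

#' ROC curve and area
#'
#' True-positive rate against false-positive rate over all score thresholds.
#' Tied scores form one threshold block, so the area (trapezoidal over the
#' staircase) equals the Mann-Whitney probability with ties counted one half.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores real-valued scores (higher = more positive).
#' @return list with \code{curve} (data.frame threshold/fpr/tpr) and
#'   \code{auc}.
#' @export
roc_curve_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0) stop("both classes must be present for ROC")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # end of each tied block
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Precision-recall curve and area
#'
#' Precision against recall over all score thresholds (tied scores form one
#' block). The area is the step-wise, non-interpolated sum
#' \eqn{\sum_i (r_i - r_{i-1}) p_i}.
#'
#' @param y_true 0/1 labels; at least one positive required.
#' @param scores real-valued scores.
#' @return list with \code{curve} (threshold/recall/precision) and \code{auc}.
#' @export
pr_curve_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  np <- sum(y_true == 1)
  if (np == 0) stop("at least one positive required for PR")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]; npred <- seq_along(y)[keep]
  recall <- tp / np; precision <- tp / npred
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[keep], recall = recall,
                          precision = precision),
       auc = auc)
}

#' One-vs-rest multiclass evaluation
#'
#' For each subtype, binarises the labels (that subtype vs rest), takes
#' ROC/PR areas from the subtype's probability column, and accuracy/F1 from
#' the hard predictions. Overall scores are unweighted means over the
#' subtypes. A subtype absent from \code{y_true} yields \code{NA} per-class
#' scores and is excluded from the overall means with a warning.
#'
#' @param y_true true subtype labels.
#' @param proba sample-by-class probability matrix (columns named by class);
#'   rows must sum to 1.
#' @param y_pred hard predicted labels; default argmax of \code{proba}.
#' @param classes class vocabulary (default the four subtypes).
#' @return an object of class \code{metrics_report}: \code{per_class}
#'   data.frame, \code{overall} named vector, \code{confusion} count matrix.
#' @export
evaluate_multiclass <- function(y_true, proba, y_pred = NULL,
                                classes = SUBTYPES) {
  proba <- as.matrix(proba)
  if (max(abs(rowSums(proba) - 1)) > 1e-6) stop("probability rows must sum to 1")
  if (is.null(y_pred)) y_pred <- colnames(proba)[max.col(proba, "first")]
  per <- data.frame(subtype = classes, auROC = NA_real_, auPRC = NA_real_,
                    accuracy = NA_real_, F1 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    yt <- as.integer(y_true == cl)
    if (!any(yt == 1)) {
      warning("subtype ", cl, " absent from y_true; excluded from overall means")
      next
    }
    yp <- as.integer(y_pred == cl)
    per$auROC[i] <- roc_curve_auc(yt, proba[, cl])$auc
    per$auPRC[i] <- pr_curve_auc(yt, proba[, cl])$auc
    af <- accuracy_f1(binary_counts(yt, yp))
    per$accuracy[i] <- af[["accuracy"]]
    per$F1[i] <- af[["F1"]]
  }
  overall <- colMeans(per[, c("auROC", "auPRC", "accuracy", "F1")], na.rm = TRUE)
  conf <- table(factor(y_true, levels = classes),
                factor(y_pred, levels = classes))
  structure(list(per_class = per, overall = overall,
                 confusion = unclass(conf)),
            class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  print(cbind(x$per_class[1], round(x$per_class[-1], digits)), row.names = FALSE)
  cat("overall:", paste(sprintf("%s=%.*f", names(x$overall), digits, x$overall),
                        collapse = " "), "\n")
  invisible(x)
}

#' Cross-tabulate two subtype label sets
#'
#' Counts of (a, b) pairs over the same samples, row-normalised percentages,
#' and the subtype-switch rate (off-diagonal fraction).
#'
#' @param labels_a,labels_b label vectors over the same samples.
#' @param classes label vocabulary.
#' @return list with \code{counts}, \code{row_percent}, \code{switch_rate}.
#' @export
cross_tabulate <- function(labels_a, labels_b, classes = SUBTYPES) {
  if (length(labels_a) != length(labels_b)) stop("label sets must cover the same samples")
  counts <- unclass(table(factor(labels_a, levels = classes),
                          factor(labels_b, levels = classes)))
  rs <- rowSums(counts)
  pct <- 100 * counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, row_percent = pct,
       switch_rate = 1 - sum(diag(counts)) / sum(counts))
}

#' Flatten a metrics report to a long table
#'
#' One row per (subtype, metric) with the score and the overall
#' (class-averaged) score, mirroring the usual benchmark-table layout.
#'
#' @param report a \code{metrics_report}.
#' @param classifier optional classifier name column.
#' @return a data.frame.
#' @export
metrics_table <- function(report, classifier = NA_character_) {
  per <- report$per_class
  out <- do.call(rbind, lapply(c("auROC", "auPRC", "accuracy", "F1"), function(m)
    data.frame(classifier = classifier, subtype = per$subtype, metric = m,
               score = per[[m]], overall = report$overall[[m]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
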