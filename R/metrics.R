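#' Confusion matrix
#'
#' Cross-tabulates true versus predicted rhythm labels: rows are true
#' classes, columns predicted classes, both in canonical order
#' (NSR, ST, SB, SVT, VT).
#'
#' @param y_true,y_pred equal-length non-empty character vectors of labels
#'   drawn from `RHYTHM_CLASSES`.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be equal-length non-empty vectors",
         call. = FALSE)
  assert_rhythm_label(y_true)
  assert_rhythm_label(y_pred)
  tt <- factor(y_true, levels = RHYTHM_CLASSES)
  pp <- factor(y_pred, levels = RHYTHM_CLASSES)
  cm <- unclass(table(true = tt, predicted = pp))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest outcome counts for a class
#'
#' @param cm a [confusion()] matrix.
#' @param class the positive class.
#' @return list with `TP`, `FP`, `FN`, `TN`; their sum equals the matrix
#'   total.
#' @export
one_vs_rest <- function(cm, class) {
  assert_rhythm_label(class)
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
       TN = as.integer(tn))
}

#' Per-class evaluation battery
#'
#' For every class, computes one-vs-rest Accuracy, Sensitivity (recall),
#' Specificity, Precision, and F1 as percentages:
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN), \quad Se = TP/(TP+FN), \quad
#'   Sp = TN/(TN+FP), \quad Pre = TP/(TP+FP), \quad
#'   F1 = 2 \cdot Se \cdot Pre / (Se + Pre).}
#' Overall accuracy is the recording-level trace over total. Metrics with a
#' zero denominator are reported as `NA` (flagged, never silently zero). If
#' per-recording class scores are supplied, a one-vs-rest ROC AUC column is
#' added.
#'
#' @param cm a [confusion()] matrix.
#' @param scores optional numeric matrix of per-recording class scores (one
#'   row per recording, columns in canonical class order) for AUC.
#' @param y_true true labels matching `scores` rows (required with
#'   `scores`).
#' @return object of class `metrics_report`: list with `per_class`
#'   (data.frame of percentages and AUC fractions), `overall_accuracy`
#'   (percent), and `confusion`.
#' @export
per_class_metrics <- function(cm, scores = NULL, y_true = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  rows <- lapply(RHYTHM_CLASSES, function(cl) {
    o <- one_vs_rest(cm, cl)
    safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    se <- safe(o$TP, o$TP + o$FN)
    pre <- safe(o$TP, o$TP + o$FP)
    f1 <- if (is.na(se) || is.na(pre) || (se + pre) == 0) NA_real_
          else 2 * se * pre / (se + pre)
    data.frame(class = cl,
               acc = safe(o$TP + o$TN, total),
               se = se,
               sp = safe(o$TN, o$TN + o$FP),
               pre = pre,
               f1 = f1,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  if (!is.null(scores)) {
    if (is.null(y_true))
      stop("y_true is required when scores are supplied", call. = FALSE)
    scores <- as_prob_matrix(scores)
    per_class$auc <- vapply(RHYTHM_CLASSES, function(cl) {
      pos <- y_true == cl
      if (all(pos) || all(!pos)) return(NA_real_)
      roc_auc(scores[, cl], pos)
    }, numeric(1))
  }
  structure(list(per_class = per_class,
                 overall_accuracy = 100 * sum(diag(cm)) / total,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  df <- x$per_class
  pct_cols <- intersect(names(df), c("acc", "se", "sp", "pre", "f1"))
  out <- df["class"]
  for (cl in pct_cols) out[[cl]] <- round_half_up(df[[cl]], digits)
  if ("auc" %in% names(df)) out$auc <- round(df$auc, 3)
  cat("Per-class metrics (%):\n")
  print(out, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.1f%%\n",
              round_half_up(x$overall_accuracy, digits)))
  invisible(x)
}

#' One-vs-rest ROC AUC
#'
#' Area under the ROC curve (sensitivity against 1 - specificity over a
#' threshold sweep of the scores), computed via the equivalent
#' Mann-Whitney rank statistic with 0.5 credit for tied score pairs — i.e.
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels logical (or 0/1) vector: `TRUE` for positives.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined AUC: need at least one positive and one negative",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Write a metrics report to disk
#'
#' Writes the per-class battery as TSV (machine-readable) or Markdown
#' (human-readable table), and the confusion matrix as a labeled TSV.
#'
#' @param report a [per_class_metrics()] result.
#' @param path output file path.
#' @param format `"tsv"` or `"markdown"`.
#' @return invisibly, `path`.
#' @export
write_metrics_report <- function(report, path, format = c("tsv", "markdown")) {
  stopifnot(inherits(report, "metrics_report"))
  format <- match.arg(format)
  df <- report$per_class
  if (format == "tsv") {
    out <- rbind(df,
                 data.frame(class = "Total", acc = report$overall_accuracy,
                            se = NA, sp = NA, pre = NA, f1 = NA,
                            auc = if ("auc" %in% names(df)) NA else NULL))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    fmt <- function(v) ifelse(is.na(v), "-",
                              sprintf("%.1f%%", round_half_up(v, 1)))
    has_auc <- "auc" %in% names(df)
    hdr <- c("Class", "Accuracy", "Sensitivity", "Specificity", "Precision",
             "F1-Score", if (has_auc) "AUC")
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"),
                      "|"))
    for (i in seq_len(nrow(df))) {
      cells <- c(df$class[i], fmt(df$acc[i]), fmt(df$se[i]), fmt(df$sp[i]),
                 fmt(df$pre[i]), fmt(df$f1[i]),
                 if (has_auc) sprintf("%.3f", df$auc[i]))
      lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
    }
    lines <- c(lines, paste0("| Total | ",
                             fmt(report$overall_accuracy),
                             " | - | - | - | - |",
                             if (has_auc) " - |" else ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a confusion matrix as TSV
#'
#' @param cm a [confusion()] matrix.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_confusion <- function(cm, path) {
  df <- as.data.frame.matrix(unclass(cm))
  df <- cbind(true = rownames(df), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
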