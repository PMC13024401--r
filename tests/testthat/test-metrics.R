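test_that("confusion matrices tabulate in canonical order", {
  y <- c("NSR", "NSR", "VT")
  p <- c("NSR", "SB", "VT")
  cm <- confusion(y, p)
  expect_identical(dim(unclass(cm)), c(5L, 5L))
  expect_identical(unname(cm["NSR", "NSR"]), 1L)
  expect_identical(unname(cm["NSR", "SB"]), 1L)
  expect_identical(unname(cm["VT", "VT"]), 1L)
  expect_identical(sum(cm), 3L)

  # perfect prediction: diagonal with trace n
  yy <- sample(RHYTHM_CLASSES, 40, replace = TRUE)
  cmp <- confusion(yy, yy)
  expect_identical(sum(diag(cmp)), 40L)
  expect_identical(sum(cmp) - sum(diag(cmp)), 0L)

  # order invariance
  set.seed(2)
  yp <- sample(RHYTHM_CLASSES, 40, replace = TRUE)
  perm <- sample(40)
  expect_identical(unclass(confusion(yy[perm], yp[perm])),
                   unclass(confusion(yy, yp)))

  expect_error(confusion(yy, yp[1:10]), "equal-length")
  expect_error(confusion(c("NSR"), c("AF")), "invalid rhythm label")
})

test_that("one-vs-rest counts decompose the matrix exactly", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:300, 1)
    cm <- confusion(sample(RHYTHM_CLASSES, n, replace = TRUE),
                    sample(RHYTHM_CLASSES, n, replace = TRUE))
    for (cl in RHYTHM_CLASSES) {
      o <- one_vs_rest(cm, cl)
      expect_identical(o$TP + o$FP + o$FN + o$TN, n)
      expect_identical(o$TP, unname(cm[cl, cl]))
      expect_identical(o$TP + o$FN, unname(sum(cm[cl, ])))
    }
  }
})

test_that("sensitivities recomputed from published outcome counts round to the reported cells", {
  # build a matrix with the stated true/correct counts in three classes
  y_true <- c(rep("NSR", 351), rep("SB", 600), rep("VT", 116))
  y_pred <- c(rep("NSR", 342), rep("SB", 9),    # 342 of 351 NSR correct
              rep("SB", 594), rep("NSR", 6),    # 594 of 600 SB correct
              rep("VT", 116))                   # 116 of 116 VT correct
  cm <- confusion(y_true, y_pred)
  rep_ <- per_class_metrics(cm)
  se <- setNames(rep_$per_class$se, rep_$per_class$class)
  expect_identical(ecgrhythm:::round_half_up(se["NSR"], 1), c(NSR = 97.4))
  expect_identical(ecgrhythm:::round_half_up(se["SB"], 1), c(SB = 99.0))
  expect_identical(ecgrhythm:::round_half_up(se["VT"], 1), c(VT = 100.0))
})

test_that("F1 is the harmonic mean of sensitivity and precision", {
  # hand case matching a published row: Se 90.3, Pre 86.2 -> F1 88.2
  f1 <- 2 * 90.3 * 86.2 / (90.3 + 86.2)
  expect_identical(ecgrhythm:::round_half_up(f1, 1), 88.2)

  # harmonic-mean identity holds on every reported row of random matrices
  set.seed(11)
  for (i in 1:10) {
    n <- sample(50:400, 1)
    cm <- confusion(sample(RHYTHM_CLASSES, n, replace = TRUE),
                    sample(RHYTHM_CLASSES, n, replace = TRUE))
    df <- per_class_metrics(cm)$per_class
    ok <- !is.na(df$se) & !is.na(df$pre) & (df$se + df$pre) > 0
    expect_equal(df$f1[ok], 2 * df$se[ok] * df$pre[ok] / (df$se + df$pre)[ok],
                 tolerance = 1e-12)
    # conservation: per-class TP sums to the trace
    tps <- vapply(RHYTHM_CLASSES, function(cl) one_vs_rest(cm, cl)$TP,
                  integer(1))
    expect_identical(sum(tps), sum(diag(cm)))
  }
})

test_that("undefined metrics are flagged as NA, not zero", {
  # nothing predicted SVT -> precision undefined for SVT
  cm <- confusion(c("SVT", "SVT", "NSR"), c("ST", "ST", "NSR"))
  df <- per_class_metrics(cm)$per_class
  expect_true(is.na(df$pre[df$class == "SVT"]))
  expect_true(is.na(df$f1[df$class == "SVT"]))
  expect_identical(df$se[df$class == "SVT"], 0)
})

test_that("AUC matches hand cases and the exhaustive pair-count oracle", {
  # perfectly separated
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
                   1)
  # constant scores: chance level
  expect_identical(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # 4-record case: 3 of 4 positive-negative pairs concordant
  expect_identical(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "undefined AUC")

  set.seed(3)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(stats::runif(n), sample(1:3, 1))  # force some ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- stats::rnorm(n, mean = labels)
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-9)
  }
})

test_that("report writers produce the published table layout", {
  y <- rep(RHYTHM_CLASSES, each = 10)
  set.seed(4)
  p <- ifelse(stats::runif(50) < 0.8, y, sample(RHYTHM_CLASSES, 50,
                                                replace = TRUE))
  cm <- confusion(y, p)
  scores <- t(vapply(match(p, RHYTHM_CLASSES), function(i) {
    v <- rep(0.05, 5); v[i] <- 0.8; v
  }, numeric(5)))
  rep_ <- per_class_metrics(cm, scores = scores, y_true = y)
  expect_true(all(rep_$per_class$auc >= 0 & rep_$per_class$auc <= 1))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(rep_, tsv)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 6L)  # 5 classes + overall row
  expect_identical(tab$class, c(RHYTHM_CLASSES, "Total"))

  md <- withr::local_tempfile(fileext = ".md")
  write_metrics_report(rep_, md, format = "markdown")
  lines <- readLines(md)
  expect_identical(length(lines), 2L + 5L + 1L)
  expect_match(lines[1], "Accuracy \\| Sensitivity")

  cmf <- withr::local_tempfile(fileext = ".tsv")
  write_confusion(cm, cmf)
  back <- utils::read.delim(cmf)
  expect_identical(unname(as.matrix(back[, -1])), matrix(as.integer(cm), 5),
                   ignore_attr = TRUE)
})
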