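#' Reduced-scale demonstration configuration
#'
#' A scaled-down variant of the classifier used for CPU-budget end-to-end
#' demonstrations and tests: `d_model = 64`, 2 encoder layers, 4 attention
#' heads (key width 8), feed-forward width 128, dropout 0.1, classification
#' head width 32. The architecture is unchanged; only widths and depth
#' shrink.
#'
#' @param ... overrides passed to [model_config()].
#' @return a [model_config()].
#' @export
reduced_model_config <- function(...) {
  args <- list(d_model = 64L, n_layers = 2L, n_heads = 4L, key_dim = 8L,
               ffn_dim = 128L, dropout = 0.1, head_hidden = 32L, l2 = 1e-4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_config, args)
}

#' Training control for the reduced-scale configuration
#'
#' Companion to [reduced_model_config()]: Adam at learning rate 2e-3 with
#' warmup, batches of 64 windows, up to 9 epochs with early-stopping
#' patience 4, a 25-sample window stride, 16 windows resampled per recording
#' per epoch, and 16 validation windows per recording for model selection.
#'
#' @param seed integer seed for initialization, window sampling, and dropout.
#' @param ... overrides passed to [train_control()].
#' @return a [train_control()].
#' @export
reduced_train_control <- function(seed = 1L, ...) {
  args <- list(lr = 2e-3, batch_size = 64L, max_epochs = 10L, patience = 5L,
               stride = 25L, windows_per_record = 16L,
               val_windows_per_record = 16L, lr_schedule = "cosine",
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_control, args)
}

#' Predict the rhythm of one recording
#'
#' Full inference pipeline for a 10 s strip: resample to 250 Hz, z-score
#' normalize over the whole strip, cut sliding windows, classify every
#' window, and fuse the window predictions by majority vote. At the default
#' window length (250) and stride (5) a 10 s recording contributes
#' `m = 451` window votes.
#'
#' @param object a [fit_rhythm_model()] result or a bare [init_model()]
#'   model.
#' @param rec an [ecg_record()] standardizable to 2500 samples at 250 Hz.
#' @param stride window stride in samples; defaults to the stride the model
#'   was trained with (5 for a bare model).
#' @param crop passed to [standardize_record()] for longer records.
#' @return a `recording_prediction` (see [majority_vote()]).
#' @export
predict_recording <- function(object, rec, stride = NULL, crop = FALSE) {
  model <- as_rhythm_model(object)
  if (is.null(stride))
    stride <- if (inherits(object, "rhythm_fit")) object$control$stride else 5L
  std <- standardize_record(rec, crop = crop)
  wb <- slide_windows(std, W = model$cfg$window_len, S = stride)
  probs <- classify_windows(model, wb$windows)
  majority_vote(probs, record_id = rec$source_id)
}

as_rhythm_model <- function(object) {
  if (inherits(object, "rhythm_fit")) object$model
  else if (inherits(object, "rhythm_model")) object
  else stop("object must be a rhythm_fit or rhythm_model", call. = FALSE)
}

#' Evaluate a classifier on labeled recordings
#'
#' Produces recording-level predictions for every record, the 5x5 confusion
#' matrix, and the per-class metric battery including one-vs-rest ROC AUC
#' computed from the recording-level mean window probabilities.
#'
#' @param object a `rhythm_fit`, a `rhythm_model`, or a function
#'   `function(rec) -> recording_prediction` (e.g. a reference classifier in
#'   tests).
#' @param records list of labeled [ecg_record()]s.
#' @param stride window stride for model-based prediction.
#' @param crop passed to [standardize_record()].
#' @return object of class `evaluation`: list with `report` (a
#'   [per_class_metrics()] result), `confusion`, and `predictions` (the
#'   [predictions_table()] data.frame).
#' @export
evaluate_model <- function(object, records, stride = NULL, crop = FALSE) {
  if (length(records) == 0)
    stop("configuration error: empty record list", call. = FALSE)
  y_true <- vapply(records, function(r) {
    if (is.null(r$label))
      stop("all records must be labeled for evaluation", call. = FALSE)
    r$label
  }, character(1))
  assert_rhythm_label(y_true)
  preds <- if (is.function(object)) {
    lapply(records, object)
  } else {
    lapply(records, function(r) predict_recording(object, r, stride = stride,
                                                  crop = crop))
  }
  y_pred <- vapply(preds, `[[`, character(1), "label")
  scores <- t(vapply(preds, `[[`,
                     numeric(length(preds[[1]]$mean_probs)), "mean_probs"))
  colnames(scores) <- names(preds[[1]]$mean_probs) %||%
    RHYTHM_CLASSES[seq_len(ncol(scores))]
  cm <- confusion(y_true, y_pred)
  report <- per_class_metrics(cm, scores = scores, y_true = y_true)
  structure(list(report = report, confusion = cm,
                 predictions = predictions_table(preds, y_true)),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  print(x$report)
  invisible(x)
}
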