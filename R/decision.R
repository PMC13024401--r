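#' Majority vote over window predictions
#'
#' Fuses the window-level predictions of one recording into a single rhythm
#' label: each window casts a hard vote for the argmax of its probability
#' vector, and the recording label is the most frequent vote,
#' \eqn{\hat y = \arg\max_c \sum_j 1[C_j(x) = c]}. The result is invariant
#' to window order. Ties are broken deterministically: among tied classes
#' the one with the highest mean softmax probability wins, with the
#' canonical class order (NSR, ST, SB, SVT, VT) as the final fallback.
#'
#' @param window_preds matrix of window probabilities (one row per window,
#'   columns in canonical class order), or a list of
#'   [classify_window()] results.
#' @param record_id identifier carried into the result.
#' @return object of class `recording_prediction`: list with `record_id`,
#'   `vote_counts` (named integer vector), `label`, `mean_probs`, and `m`
#'   (number of windows voted).
#' @export
majority_vote <- function(window_preds, record_id = "") {
  probs <- as_prob_matrix(window_preds)
  m <- nrow(probs)
  if (m < 1) stop("window_preds must be non-empty", call. = FALSE)
  classes <- colnames(probs)
  hard <- max.col(probs, ties.method = "first")
  counts <- tabulate(hard, nbins = ncol(probs))
  names(counts) <- classes
  mean_probs <- colMeans(probs)
  top <- which(counts == max(counts))
  winner <- if (length(top) == 1) top else {
    best <- top[mean_probs[top] == max(mean_probs[top])]
    best[1]  # canonical class order as final fallback
  }
  structure(list(record_id = record_id,
                 vote_counts = stats::setNames(as.integer(counts), classes),
                 label = classes[winner],
                 mean_probs = mean_probs,
                 m = m),
            class = "recording_prediction")
}

#' Recording-level probability vector
#'
#' Arithmetic mean of the window probability vectors; stays on the
#' probability simplex. Used as the recording-level score for one-vs-rest
#' ROC analysis.
#'
#' @inheritParams majority_vote
#' @return numeric vector of length `n_classes` summing to 1.
#' @export
recording_probability <- function(window_preds) {
  probs <- as_prob_matrix(window_preds)
  if (nrow(probs) < 1) stop("window_preds must be non-empty", call. = FALSE)
  colMeans(probs)
}

as_prob_matrix <- function(window_preds) {
  if (is.list(window_preds) && !is.data.frame(window_preds) &&
      !is.matrix(window_preds)) {
    if (length(window_preds) == 0)
      stop("window_preds must be non-empty", call. = FALSE)
    probs <- do.call(rbind, lapply(window_preds, function(wp) {
      if (inherits(wp, "window_prediction")) wp$probs else as.numeric(wp)
    }))
  } else {
    probs <- as.matrix(window_preds)
  }
  if (is.null(colnames(probs)))
    colnames(probs) <- RHYTHM_CLASSES[seq_len(ncol(probs))]
  probs
}

#' @export
print.recording_prediction <- function(x, ...) {
  cat(sprintf("<recording_prediction> %s -> %s (%d/%d votes)\n",
              if (nzchar(x$record_id)) x$record_id else "(unnamed)",
              x$label, x$vote_counts[x$label], x$m))
  invisible(x)
}

#' Export recording predictions as a table
#'
#' @param preds list of `recording_prediction`s.
#' @param true_labels optional character vector of ground-truth labels.
#' @return data.frame with record id, labels, vote counts, and mean
#'   probabilities per class.
#' @export
predictions_table <- function(preds, true_labels = NULL) {
  classes <- names(preds[[1]]$vote_counts)
  df <- data.frame(
    record_id = vapply(preds, `[[`, character(1), "record_id"),
    true_label = if (is.null(true_labels)) NA_character_ else true_labels,
    pred_label = vapply(preds, `[[`, character(1), "label"),
    m = vapply(preds, `[[`, integer(1), "m"),
    stringsAsFactors = FALSE
  )
  votes <- t(vapply(preds, `[[`, integer(length(classes)), "vote_counts"))
  colnames(votes) <- paste0("votes_", classes)
  probs <- t(vapply(preds, `[[`, numeric(length(classes)), "mean_probs"))
  colnames(probs) <- paste0("prob_", classes)
  cbind(df, votes, probs)
}
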