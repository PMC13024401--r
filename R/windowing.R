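#' Decompose a recording into sliding windows
#'
#' Cuts the sample vector into fixed-length windows of `W` samples taken
#' every `S` samples: window `j` (0-based) covers the half-open sample range
#' `[j*S, j*S + W)`. The number of windows is `floor((L - W) / S) + 1`; any
#' trailing remainder shorter than `W` is dropped. At the defaults (10 s at
#' 250 Hz, `W = 250`, `S = 5`) a recording yields 451 windows. Every window
#' inherits the parent recording's rhythm label.
#'
#' @param rec an [ecg_record()] (typically standardized), or a bare numeric
#'   vector.
#' @param W window length in samples (default 250, i.e. 1 s at 250 Hz).
#' @param S stride in samples (default 5).
#' @return object of class `window_batch`: list with `windows` (matrix, one
#'   window per row), `starts` (0-based start indices), `W`, `S`,
#'   `parent_id`, and `label`.
#' @export
slide_windows <- function(rec, W = 250L, S = 5L) {
  if (inherits(rec, "ecg_record")) {
    x <- rec$samples
    parent_id <- rec$source_id
    label <- rec$label
  } else {
    x <- as.numeric(rec)
    parent_id <- ""
    label <- NULL
  }
  W <- as.integer(W); S <- as.integer(S)
  if (W < 1 || S < 1) stop("W and S must be >= 1", call. = FALSE)
  L <- length(x)
  if (L < W)
    stop("input too short: ", L, " samples, window needs ", W, call. = FALSE)
  n_win <- (L - W) %/% S + 1L
  starts <- (seq_len(n_win) - 1L) * S  # 0-based
  idx <- outer(starts, seq_len(W) - 1L, `+`) + 1L
  windows <- matrix(x[idx], nrow = n_win, ncol = W)
  structure(list(windows = windows, starts = starts, W = W, S = S,
                 parent_id = parent_id, label = label),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  cat(sprintf("<window_batch> %d windows of %d samples (stride %d) from %s%s\n",
              nrow(x$windows), x$W, x$S,
              if (nzchar(x$parent_id)) x$parent_id else "(unnamed)",
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Window count arithmetic for a dataset
#'
#' Number of window samples produced by sliding-window decomposition of
#' `n_records` recordings of length `L`: `n_records * (floor((L - W)/S) + 1)`.
#' Pure arithmetic; no data is touched. At the defaults (300 recordings of
#' 2500 samples, `W = 250`, `S = 5`) this is 135,300.
#'
#' @param n_records number of recordings.
#' @param L recording length in samples (default 2500).
#' @param W window length in samples (default 250).
#' @param S stride in samples (default 5).
#' @return integer window count.
#' @export
augmentation_count <- function(n_records, L = 2500L, W = 250L, S = 5L) {
  if (n_records < 1 || n_records != round(n_records))
    stop("n_records must be a positive integer", call. = FALSE)
  if (W < 1 || S < 1) stop("W and S must be >= 1", call. = FALSE)
  if (L < W) stop("input too short: L < W", call. = FALSE)
  as.integer(n_records) * (((as.integer(L) - as.integer(W)) %/%
                              as.integer(S)) + 1L)
}
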