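#' Rhythm class labels
#'
#' The five rhythm categories handled by the package, in canonical order:
#' normal sinus rhythm (NSR), sinus tachycardia (ST), sinus bradycardia (SB),
#' supraventricular tachycardia (SVT, pooled with atrial tachycardia), and
#' ventricular tachycardia (VT). This order is used for class probability
#' vectors, confusion-matrix rows/columns, and tie-breaking.
#'
#' @export
RHYTHM_CLASSES <- c("NSR", "ST", "SB", "SVT", "VT")

# Validate a label (or vector of labels) against the admissible set.
assert_rhythm_label <- function(label) {
  bad <- setdiff(as.character(label), RHYTHM_CLASSES)
  if (length(bad) > 0) {
    stop("invalid rhythm label(s): ", paste(bad, collapse = ", "),
         " (must be one of ", paste(RHYTHM_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(as.character(label))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministically combine seed components into one 32-bit seed.
combine_seeds <- function(...) {
  parts <- as.integer(c(...))
  s <- 0L
  for (p in parts) {
    s <- bitwXor(s * 31L + p, bitwShiftL(p, 7L))
    s <- s %% 2147483647L
  }
  abs(s)
}

#' Softmax transform
#'
#' Maps a vector of logits \eqn{z} to a probability distribution
#' \eqn{p_i = e^{z_i} / \sum_j e^{z_j}}. For a matrix, the transform is
#' applied row-wise. Numerically stabilized by subtracting the row maximum.
#'
#' @param z numeric vector of logits, or a matrix with one logit vector per
#'   row.
#' @return object of the same shape as `z` with non-negative entries summing
#'   to 1 (per row).
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    rmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
    e <- exp(z - rmax)  # column-major recycling subtracts rmax[i] per row
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

# round() uses banker's rounding; reports follow the half-up convention used
# for one-decimal percentage tables.
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
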