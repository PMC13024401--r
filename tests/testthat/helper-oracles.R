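# Independent oracles used to check package computations. These stay
# deliberately naive: thresholding, brute-force enumeration, and dense
# matrix arithmetic, written without reference to the implementation paths
# they verify.

# Threshold-based R-peak detector for clean (noise-off) synthetic signals:
# local maxima above half the global maximum, at least 150 ms apart.
oracle_detect_peaks <- function(x, fs) {
  th <- 0.5 * max(x)
  n <- length(x)
  is_peak <- x > th & x >= c(-Inf, x[-n]) & x > c(x[-1], Inf)
  pk <- which(is_peak)
  if (length(pk) <= 1) return(pk)
  keep <- pk[1]
  for (p in pk[-1]) if (p - keep[length(keep)] > 0.15 * fs) keep <- c(keep, p)
  keep
}

# Mean instantaneous heart rate (bpm) from detected peak sample indices.
oracle_mean_hr <- function(peaks, fs) {
  mean(60 / diff(peaks / fs))
}

# Brute-force majority vote: frequency table over hard labels.
oracle_vote <- function(probs) {
  hard <- apply(probs, 1, which.max)
  tab <- table(factor(hard, levels = seq_len(ncol(probs))))
  which(tab == max(tab))  # all argmax candidates
}

# Exhaustive concordant-pair AUC with 0.5 credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
                 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force enumeration of valid window start indices (0-based).
oracle_window_starts <- function(L, W, S) {
  starts <- integer(0)
  s <- 0L
  while (s + W <= L) { starts <- c(starts, s); s <- s + S }
  starts
}

# Dense single-head attention: direct evaluation of the defining equations.
oracle_attention <- function(Q, K, V, d_k) {
  S <- Q %*% t(K) / sqrt(d_k)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  if (nrow(S) == 1) A <- matrix(A, 1)
  A %*% V
}

# Dense multi-head attention with per-head projections and output projection.
oracle_multi_head <- function(X, w, n_heads, key_dim) {
  heads <- lapply(seq_len(n_heads), function(h) {
    cols <- ((h - 1) * key_dim + 1):(h * key_dim)
    oracle_attention(X %*% w$Wq[, cols, drop = FALSE],
                     X %*% w$Wk[, cols, drop = FALSE],
                     X %*% w$Wv[, cols, drop = FALSE], key_dim)
  })
  do.call(cbind, heads) %*% w$Wo
}

# Small labeled synthetic dataset shared across tests (clean, fast).
make_clean_config <- function(per_class = 5, seed = 101) {
  synth_config(per_class_count = per_class, seed = seed, noise = noise_off())
}

# Tiny model configuration for fast structural tests.
tiny_config <- function(...) {
  args <- list(d_model = 8L, n_layers = 1L, n_heads = 2L, key_dim = 4L,
               ffn_dim = 16L, dropout = 0, l2 = 0, t2v_k = 2L,
               window_len = 40L, head_hidden = 8L)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}
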