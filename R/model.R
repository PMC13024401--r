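#' Model configuration
#'
#' Architectural hyperparameters of the window-level Time2Vec-transformer
#' classifier. Defaults follow the reference configuration: a 3-layer
#' encoder of width `d_model = 256` with 12 attention heads, a feed-forward
#' width of 1024, dropout 0.25, and L2 regularization 0.001, classifying
#' 250-sample (1 s at 250 Hz) windows into 5 rhythm classes. `key_dim` is an
#' independent per-head query/key width (the concatenated heads,
#' `n_heads * key_dim` wide, are projected back to `d_model`), so `n_heads`
#' need not divide `d_model`.
#'
#' @param d_model embedding width.
#' @param n_layers encoder depth.
#' @param n_heads attention heads.
#' @param key_dim per-head query/key/value width (default 21, giving a
#'   12-head concatenation of width 252 ahead of the output projection).
#' @param ffn_dim inner width of the position-wise feed-forward sublayer.
#' @param dropout dropout rate in \[0,1), applied to each sublayer output and
#'   between the two classification-head linears during training.
#' @param l2 L2 weight-decay coefficient applied to weight matrices.
#' @param t2v_k number of periodic Time2Vec components (output dimension is
#'   `t2v_k + 1`).
#' @param window_len window length in samples.
#' @param n_classes number of rhythm classes (5 for this task).
#' @param pooling pooling of encoder output before the head: `"mean"` over
#'   positions (default), `"last"` position, or `"cls"` (first position).
#' @param head_hidden width of the first classification linear layer.
#' @return object of class `model_config`.
#' @export
model_config <- function(d_model = 256L, n_layers = 3L, n_heads = 12L,
                         key_dim = 21L, ffn_dim = 1024L, dropout = 0.25,
                         l2 = 0.001, t2v_k = 2L, window_len = 250L,
                         n_classes = 5L, pooling = c("mean", "last", "cls"),
                         head_hidden = 64L) {
  pooling <- match.arg(pooling)
  widths <- c(d_model = d_model, n_heads = n_heads, key_dim = key_dim,
              ffn_dim = ffn_dim, t2v_k = t2v_k, window_len = window_len,
              n_classes = n_classes, head_hidden = head_hidden)
  if (any(widths[names(widths) != "t2v_k"] < 1) || t2v_k < 1)
    stop("all widths must be positive", call. = FALSE)
  if (n_layers < 0) stop("n_layers must be >= 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0,1)",
                                        call. = FALSE)
  if (l2 < 0) stop("l2 must be >= 0", call. = FALSE)
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), key_dim = as.integer(key_dim),
                 ffn_dim = as.integer(ffn_dim), dropout = dropout, l2 = l2,
                 t2v_k = as.integer(t2v_k),
                 window_len = as.integer(window_len),
                 n_classes = as.integer(n_classes), pooling = pooling,
                 head_hidden = as.integer(head_hidden)),
            class = "model_config")
}

#' Time2Vec temporal embedding
#'
#' Maps a vector of time indices \eqn{\tau} to a `(k+1) x length(tau)`
#' matrix: row 1 is the linear component \eqn{\omega_0 \tau + \phi_0}; rows
#' `2..k+1` are the periodic components
#' \eqn{\sin(\omega_i \tau + \phi_i)}, each bounded in \[-1, 1\]. The
#' frequencies `omega` and phases `phi` are learnable model parameters.
#'
#' @param tau numeric vector of time indices.
#' @param omega numeric vector of length `k + 1`.
#' @param phi numeric vector of length `k + 1`.
#' @return matrix of dimension `(k+1) x length(tau)`.
#' @export
time2vec <- function(tau, omega, phi) {
  if (length(omega) != length(phi))
    stop("omega and phi must have equal length", call. = FALSE)
  k1 <- length(omega)
  arg <- outer(omega, tau) + phi  # (k+1) x n
  out <- sin(arg)
  out[1, ] <- arg[1, ]
  out
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a rhythm classification model
#'
#' Builds all trainable parameters of the Time2Vec-transformer classifier
#' with Glorot-style uniform initialization (biases and layer-norm offsets
#' zero, layer-norm gains one). Time2Vec frequencies are initialized small;
#' the time index within a window is the integer sample index
#' `0..window_len-1`.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed recorded in the model; initialization is a pure
#'   function of `(cfg, seed)`.
#' @return object of class `rhythm_model`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$d_model; hd <- cfg$n_heads * cfg$key_dim
  k1 <- cfg$t2v_k + 1L
  with_seed(combine_seeds(seed, 104729L), {
    params <- list(
      # linear frequency scaled so omega_0 * tau stays O(1) over the window:
      # an unscaled ramp dwarfs the signal projection and the encoder
      # collapses to an input-independent state on some seeds
      t2v_omega = c(stats::runif(1, -1, 1) / cfg$window_len,
                    stats::runif(cfg$t2v_k, 0.01, 0.3)),
      t2v_phi = c(stats::runif(1, -0.1, 0.1),
                  stats::runif(cfg$t2v_k, -pi, pi)),
      w_sig = as.numeric(glorot(1L, d)),
      b_emb = numeric(d),
      W_t2v = glorot(k1, d),
      layers = lapply(seq_len(cfg$n_layers), function(l) list(
        Wq = glorot(d, hd), bq = numeric(hd),
        Wk = glorot(d, hd), bk = numeric(hd),
        Wv = glorot(d, hd), bv = numeric(hd),
        Wo = glorot(hd, d), bo = numeric(d),
        ln1_g = rep(1, d), ln1_b = numeric(d),
        W1 = glorot(d, cfg$ffn_dim), b1 = numeric(cfg$ffn_dim),
        W2 = glorot(cfg$ffn_dim, d), b2 = numeric(d),
        ln2_g = rep(1, d), ln2_b = numeric(d)
      )),
      Wh1 = glorot(d, cfg$head_hidden), bh1 = numeric(cfg$head_hidden),
      Wh2 = glorot(cfg$head_hidden, cfg$n_classes),
      bh2 = numeric(cfg$n_classes)
    )
    structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
              class = "rhythm_model")
  })
}

#' @export
print.rhythm_model <- function(x, ...) {
  cat(sprintf(paste0("<rhythm_model> d_model=%d, %d layers, %d heads ",
                     "(key_dim %d), ffn %d, %s parameters\n"),
              x$cfg$d_model, x$cfg$n_layers, x$cfg$n_heads, x$cfg$key_dim,
              x$cfg$ffn_dim, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in the model (all weight matrices,
#' biases, layer-norm gains/offsets, and Time2Vec frequencies/phases).
#'
#' @param model a [init_model()] result.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "rhythm_model"))
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  as.integer(count(model$params))
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K^T / sqrt(d_k)) V`. Attention-weight rows sum to 1.
#'
#' @param Q query matrix (`n_q x d_k`).
#' @param K key matrix (`n_kv x d_k`).
#' @param V value matrix (`n_kv x d_v`).
#' @param d_k key width used in the scaling (defaults to `ncol(K)`).
#' @return list with `output` (`n_q x d_v`) and `weights` (`n_q x n_kv`).
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop("Q and K must have the same width", call. = FALSE)
  if (nrow(K) != nrow(V))
    stop("K and V must have the same number of rows", call. = FALSE)
  A <- softmax(Q %*% t(K) / sqrt(d_k))
  if (!is.matrix(A)) A <- matrix(A, nrow = nrow(Q))
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention over one sequence
#'
#' Applies `n_heads` parallel scaled dot-product attentions over learned
#' per-head projections of `X`, concatenates the head outputs, and projects
#' back to the model width with the output matrix `Wo`. With one head and
#' identity projections this reduces exactly to [scaled_dot_attention()].
#'
#' @param X sequence matrix (`seq_len x d_model`).
#' @param weights list with `Wq`, `Wk`, `Wv` (`d_model x n_heads*key_dim`),
#'   `Wo` (`n_heads*key_dim x d_model`), and optional biases `bq`, `bk`,
#'   `bv`, `bo`.
#' @param n_heads number of heads.
#' @param key_dim per-head width.
#' @return matrix of the same shape as `X`.
#' @export
multi_head_attention <- function(X, weights, n_heads, key_dim) {
  X <- as.matrix(X)
  hd <- n_heads * key_dim
  if (ncol(weights$Wq) != hd || ncol(weights$Wk) != hd ||
      ncol(weights$Wv) != hd)
    stop("projection widths must equal n_heads * key_dim", call. = FALSE)
  off <- function(b, n) if (is.null(b)) numeric(n) else b
  Q <- X %*% weights$Wq + matrix(off(weights$bq, hd), nrow(X), hd,
                                 byrow = TRUE)
  K <- X %*% weights$Wk + matrix(off(weights$bk, hd), nrow(X), hd,
                                 byrow = TRUE)
  V <- X %*% weights$Wv + matrix(off(weights$bv, hd), nrow(X), hd,
                                 byrow = TRUE)
  O <- matrix(0, nrow(X), hd)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * key_dim + 1L):(h * key_dim)
    O[, cols] <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE],
                                      V[, cols, drop = FALSE],
                                      d_k = key_dim)$output
  }
  O %*% weights$Wo + matrix(off(weights$bo, ncol(weights$Wo)), nrow(X),
                            ncol(weights$Wo), byrow = TRUE)
}

#' Position-wise feed-forward sublayer
#'
#' `max(0, x W1 + b1) W2 + b2`, applied independently at every sequence
#' position (equivalent to two kernel-size-1 convolutions with a ReLU
#' between).
#'
#' @param X sequence matrix (`seq_len x d_model`).
#' @param W1,b1 first linear map (`d_model x ffn_dim`) and bias.
#' @param W2,b2 second linear map (`ffn_dim x d_model`) and bias.
#' @return matrix of the same shape as `X`.
#' @export
ffn <- function(X, W1, b1, W2, b2) {
  X <- as.matrix(X)
  H <- pmax(X %*% W1 + matrix(b1, nrow(X), length(b1), byrow = TRUE), 0)
  H %*% W2 + matrix(b2, nrow(X), length(b2), byrow = TRUE)
}

#' Layer normalization
#'
#' Normalizes each row (one feature vector / sequence position) to mean 0
#' and variance 1, then applies the learned gain and offset.
#'
#' @param X matrix, one feature vector per row.
#' @param gamma,beta gain and offset vectors of length `ncol(X)`; defaults
#'   1 and 0.
#' @param eps numerical stabilizer.
#' @return matrix of the same shape as `X`.
#' @export
layer_norm <- function(X, gamma = rep(1, ncol(X)), beta = numeric(ncol(X)),
                       eps = 1e-5) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  xhat * matrix(gamma, nrow(X), ncol(X), byrow = TRUE) +
    matrix(beta, nrow(X), ncol(X), byrow = TRUE)
}

#' One transformer encoder layer
#'
#' `LayerNorm(x + Sublayer(x))` applied around the multi-head self-attention
#' sublayer and then around the position-wise feed-forward sublayer. Dropout
#' at the configured rate is applied to each sublayer output during training
#' only.
#'
#' @param X sequence matrix (`seq_len x d_model`).
#' @param layer one element of `model$params$layers`.
#' @param cfg the [model_config()].
#' @param training apply dropout (draws from the current RNG stream).
#' @return matrix of the same shape as `X`.
#' @export
encoder_layer <- function(X, layer, cfg, training = FALSE) {
  M <- multi_head_attention(X, layer, cfg$n_heads, cfg$key_dim)
  if (training && cfg$dropout > 0) M <- dropout_mask(dim(M), cfg$dropout) * M
  X1 <- layer_norm(X + M, layer$ln1_g, layer$ln1_b)
  Fo <- ffn(X1, layer$W1, layer$b1, layer$W2, layer$b2)
  if (training && cfg$dropout > 0) Fo <- dropout_mask(dim(Fo), cfg$dropout) * Fo
  layer_norm(X1 + Fo, layer$ln2_g, layer$ln2_b)
}

# Inverted dropout mask: zeros with probability p, survivors scaled 1/(1-p).
dropout_mask <- function(dm, p) {
  matrix((stats::runif(prod(dm)) >= p) / (1 - p), dm[1], dm[2])
}

#' Embed one window
#'
#' Fuses the signal and temporal paths: each scalar sample is projected to
#' `d_model` by a learned vector, each `(k+1)`-dimensional Time2Vec column
#' is projected to `d_model` by a learned matrix, and the two are summed
#' element-wise per position (plus a shared bias).
#'
#' @param model a [init_model()] result.
#' @param window numeric vector of length `cfg$window_len`.
#' @return matrix `window_len x d_model`.
#' @export
embed_window <- function(model, window) {
  stopifnot(inherits(model, "rhythm_model"))
  cfg <- model$cfg
  if (length(window) != cfg$window_len)
    stop("window length ", length(window), " != configured ",
         cfg$window_len, call. = FALSE)
  p <- model$params
  tau <- seq_len(cfg$window_len) - 1
  T2V <- time2vec(tau, p$t2v_omega, p$t2v_phi)  # (k+1) x W
  outer(as.numeric(window), p$w_sig) + t(T2V) %*% p$W_t2v +
    matrix(p$b_emb, cfg$window_len, cfg$d_model, byrow = TRUE)
}

# ---- Batched forward pass ---------------------------------------------------
# Windows are stacked row-blocks of W positions each; position-wise ops run
# as single BLAS calls on the (B*W x d) block matrix, attention loops over
# windows and heads.

forward_batch <- function(model, windows, training = FALSE, keep = FALSE) {
  cfg <- model$cfg; p <- model$params
  if (!is.matrix(windows)) windows <- matrix(windows, nrow = 1)
  if (ncol(windows) != cfg$window_len)
    stop("window length ", ncol(windows), " != configured ",
         cfg$window_len, call. = FALSE)
  B <- nrow(windows); W <- cfg$window_len; d <- cfg$d_model
  N <- B * W
  s <- as.numeric(t(windows))            # position-fast, window-major
  tau <- seq_len(W) - 1
  T2V <- time2vec(tau, p$t2v_omega, p$t2v_phi)
  E_time <- t(T2V) %*% p$W_t2v           # W x d
  X <- addb(outer(s, p$w_sig) + E_time[rep(seq_len(W), B), ], p$b_emb)
  cache <- if (keep) list(s = s, T2V = T2V, B = B, W = W,
                          layers = vector("list", cfg$n_layers)) else NULL
  drop_p <- if (training) cfg$dropout else 0
  win_rows <- function(b) ((b - 1L) * W + 1L):(b * W)
  if (attn_single_precision() && cfg$n_layers > 0) {
    # fused single-precision encoder stack; activations cached C++-side
    enc <- .encoder_forward_cpp(X, p$layers, drop_p, B, W,
                                cfg$n_heads, cfg$key_dim, keep)
    if (keep) cache$enc_ptr <- enc$cache
    X <- enc$out
  } else for (l in seq_len(cfg$n_layers)) {
    ly <- p$layers[[l]]
    hd <- cfg$n_heads * cfg$key_dim
    Q <- addb(X %*% ly$Wq, ly$bq)
    K <- addb(X %*% ly$Wk, ly$bk)
    V <- addb(X %*% ly$Wv, ly$bv)
    O <- .attn_forward_cpp(Q, K, V, B, W, cfg$n_heads, cfg$key_dim,
                           attn_single_precision())
    M <- addb(O %*% ly$Wo, ly$bo)
    dm1 <- NULL
    if (drop_p > 0) { dm1 <- dropout_mask(c(N, d), drop_p); M <- M * dm1 }
    R1 <- X + M
    ln1 <- ln_forward(R1, ly$ln1_g, ly$ln1_b)
    X1 <- ln1$out
    H <- pmax(addb(X1 %*% ly$W1, ly$b1), 0)
    Fo <- addb(H %*% ly$W2, ly$b2)
    dm2 <- NULL
    if (drop_p > 0) { dm2 <- dropout_mask(c(N, d), drop_p); Fo <- Fo * dm2 }
    R2 <- X1 + Fo
    ln2 <- ln_forward(R2, ly$ln2_g, ly$ln2_b)
    if (keep) {
      cache$layers[[l]] <- list(X0 = X, Q = Q, K = K, V = V, O = O,
                                dm1 = dm1, xhat1 = ln1$xhat, inv1 = ln1$inv,
                                X1 = X1, H = H, dm2 = dm2,
                                xhat2 = ln2$xhat, inv2 = ln2$inv)
    }
    X <- ln2$out
  }
  grp <- rep(seq_len(B), each = W)
  P <- switch(cfg$pooling,
              mean = rowsum(X, grp, reorder = FALSE) / W,
              last = X[win_rows(1)[W] + (seq_len(B) - 1L) * W, , drop = FALSE],
              cls = X[(seq_len(B) - 1L) * W + 1L, , drop = FALSE])
  U <- pmax(addb(P %*% p$Wh1, p$bh1), 0)
  dmu <- NULL
  if (drop_p > 0) { dmu <- dropout_mask(dim(U), drop_p); Ud <- U * dmu }
  else Ud <- U
  logits <- addb(Ud %*% p$Wh2, p$bh2)
  probs <- softmax(logits)
  if (keep) {
    cache$Xenc <- X; cache$P <- P; cache$U <- U; cache$Ud <- Ud
    cache$dmu <- dmu; cache$probs <- probs
  }
  list(probs = probs, logits = logits, cache = cache)
}

# Add a bias vector to every row (column-major recycling; avoids byrow).
addb <- function(X, b) X + rep(b, each = nrow(X))

# Attention kernels run in float32 by default; tests flip this option for
# double-precision finite-difference gradient checks.
attn_single_precision <- function() {
  !isTRUE(getOption("ecgrhythm.attn_double", FALSE))
}

ln_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- xhat * matrix(gamma, nrow(X), ncol(X), byrow = TRUE) +
    matrix(beta, nrow(X), ncol(X), byrow = TRUE)
  list(out = out, xhat = xhat, inv = inv)
}

#' Classify one window
#'
#' Runs the full window-level model (embedding, encoder, pooled two-layer
#' head, softmax) on a single window with dropout disabled.
#'
#' @param model a [init_model()] result.
#' @param window numeric vector of length `cfg$window_len`.
#' @return object of class `window_prediction`: list with `probs` (length-5
#'   simplex vector, named by class) and `logits`.
#' @export
classify_window <- function(model, window) {
  fw <- forward_batch(model, matrix(as.numeric(window), nrow = 1),
                      training = FALSE)
  structure(list(probs = stats::setNames(as.numeric(fw$probs),
                                         RHYTHM_CLASSES[seq_len(model$cfg$n_classes)]),
                 logits = as.numeric(fw$logits)),
            class = "window_prediction")
}

#' Classify a batch of windows
#'
#' @param model a [init_model()] result.
#' @param windows matrix with one window per row.
#' @param chunk number of windows scored per BLAS block (bounds memory).
#' @return matrix of class probabilities, one row per window.
#' @export
classify_windows <- function(model, windows, chunk = 128L) {
  if (!is.matrix(windows)) windows <- matrix(windows, nrow = 1)
  out <- matrix(NA_real_, nrow(windows), model$cfg$n_classes)
  i <- 1L
  while (i <= nrow(windows)) {
    j <- min(i + chunk - 1L, nrow(windows))
    out[i:j, ] <- forward_batch(model, windows[i:j, , drop = FALSE])$probs
    i <- j + 1L
  }
  colnames(out) <- RHYTHM_CLASSES[seq_len(model$cfg$n_classes)]
  out
}
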