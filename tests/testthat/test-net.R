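test_that("time2vec evaluates its defining form", {
  # linear component: identity at omega_0 = 1, phi_0 = 0
  tv <- time2vec(5, omega = c(1, pi / 2, 0.3), phi = c(0, 0, 0.1))
  expect_identical(tv[1, 1], 5)
  # periodic component: sin(pi/2 * 1) = 1
  tv1 <- time2vec(1, omega = c(1, pi / 2, 0.3), phi = c(0, 0, 0))
  expect_equal(tv1[2, 1], 1)
  # shape 3 x 250 for k = 2 over a 250-sample window
  tv250 <- time2vec(0:249, omega = c(0.1, 0.2, 0.3), phi = c(0, 1, 2))
  expect_identical(dim(tv250), c(3L, 250L))
  # periodic rows bounded in [-1, 1]
  expect_true(all(abs(tv250[2:3, ]) <= 1))
})

test_that("window embedding sums projected signal and temporal paths", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 5)
  x <- stats::rnorm(cfg$window_len)
  E <- embed_window(m, x)
  expect_identical(dim(E), c(cfg$window_len, cfg$d_model))
  # zero projections produce an all-zero embedding
  m0 <- m
  m0$params$w_sig[] <- 0; m0$params$W_t2v[] <- 0; m0$params$b_emb[] <- 0
  expect_true(all(embed_window(m0, x) == 0))
  # doubling the window doubles exactly the signal-projection contribution
  diff1 <- embed_window(m, 2 * x) - embed_window(m, x)
  expect_equal(diff1, outer(x, m$params$w_sig), tolerance = 1e-12)
  expect_error(embed_window(m, stats::rnorm(10)), "window length")
})

test_that("scaled dot-product attention obeys hand-computable cases", {
  # single position: softmax of a scalar is 1, output is V
  r1 <- scaled_dot_attention(matrix(2, 1, 1), matrix(3, 1, 1),
                             matrix(7, 1, 1))
  expect_equal(r1$output[1, 1], 7)
  expect_equal(r1$weights[1, 1], 1)

  # orthogonal query, identical values: uniform weights return that value
  r2 <- scaled_dot_attention(matrix(c(0, 0), 1), matrix(c(1, 0, 0, 1), 2),
                             matrix(c(5, 5), 2, 1))
  expect_equal(as.numeric(r2$output), 5)
  expect_equal(as.numeric(r2$weights), c(0.5, 0.5))

  # two-key instance evaluated by hand: weights softmax([1/sqrt(2), 0])
  r3 <- scaled_dot_attention(Q = matrix(c(1, 0), 1), K = rbind(c(1, 0),
                                                               c(0, 1)),
                             V = matrix(c(1, 0), 2, 1), d_k = 2)
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(as.numeric(r3$weights), c(w1, 1 - w1), tolerance = 1e-12)
  expect_equal(r3$output[1, 1], w1, tolerance = 1e-12)

  # attention-weight rows always sum to 1
  set.seed(8)
  r4 <- scaled_dot_attention(matrix(rnorm(12), 3), matrix(rnorm(20), 5),
                             matrix(rnorm(10), 5))
  expect_equal(rowSums(r4$weights), rep(1, 3), tolerance = 1e-12)
  expect_error(scaled_dot_attention(matrix(1, 1, 2), matrix(1, 1, 3),
                                    matrix(1, 1, 1)), "width")
})

test_that("multi-head attention reduces to single-head and matches the dense oracle", {
  set.seed(21)
  X <- matrix(rnorm(5 * 4), 5, 4)
  # h = 1 with identity projections collapses to plain attention
  id <- diag(4)
  w1 <- list(Wq = id, Wk = id, Wv = id, Wo = id)
  expect_equal(multi_head_attention(X, w1, n_heads = 1, key_dim = 4),
               scaled_dot_attention(X, X, X)$output, tolerance = 1e-12)

  # random multi-head instances match direct dense evaluation
  for (i in 1:5) {
    n_heads <- sample(1:3, 1); key_dim <- sample(2:4, 1)
    hd <- n_heads * key_dim
    w <- list(Wq = matrix(rnorm(4 * hd), 4), Wk = matrix(rnorm(4 * hd), 4),
              Wv = matrix(rnorm(4 * hd), 4), Wo = matrix(rnorm(hd * 4), hd))
    expect_equal(multi_head_attention(X, w, n_heads, key_dim),
                 oracle_multi_head(X, w, n_heads, key_dim),
                 tolerance = 1e-9)
    # output width equals input width for any head count
    expect_identical(dim(multi_head_attention(X, w, n_heads, key_dim)),
                     dim(X))
  }

  # permuting head order with correspondingly permuted output-projection
  # rows leaves the result unchanged
  n_heads <- 3; key_dim <- 2; hd <- 6
  w <- list(Wq = matrix(rnorm(4 * hd), 4), Wk = matrix(rnorm(4 * hd), 4),
            Wv = matrix(rnorm(4 * hd), 4), Wo = matrix(rnorm(hd * 4), hd))
  perm <- c(2, 3, 1)
  colperm <- as.vector(vapply(perm, function(h) (h - 1) * key_dim + 1:2,
                              numeric(2)))
  wp <- list(Wq = w$Wq[, colperm], Wk = w$Wk[, colperm],
             Wv = w$Wv[, colperm], Wo = w$Wo[colperm, ])
  expect_equal(multi_head_attention(X, wp, n_heads, key_dim),
               multi_head_attention(X, w, n_heads, key_dim),
               tolerance = 1e-12)
})

test_that("batched attention kernel matches the dense double-precision oracle", {
  set.seed(33)
  B <- 3; W <- 6; H <- 2; dk <- 4; hd <- H * dk
  Q <- matrix(rnorm(B * W * hd), B * W)
  K <- matrix(rnorm(B * W * hd), B * W)
  V <- matrix(rnorm(B * W * hd), B * W)
  O <- ecgrhythm:::.attn_forward_cpp(Q, K, V, B, W, H, dk)
  for (b in 1:B) {
    rows <- ((b - 1) * W + 1):(b * W)
    for (h in 1:H) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      expect_equal(O[rows, cols],
                   oracle_attention(Q[rows, cols], K[rows, cols],
                                    V[rows, cols], dk),
                   tolerance = 1e-6)
    }
  }
})

test_that("feed-forward sublayer is position-wise with hand-checked scalars", {
  # scalar case: max(0, 1*2 - 1) * 3 = 3
  out <- ffn(matrix(1, 1, 1), W1 = matrix(2), b1 = -1, W2 = matrix(3), b2 = 0)
  expect_equal(out[1, 1], 3)
  # all-negative pre-activations leave only the output bias
  out2 <- ffn(matrix(1, 2, 1), W1 = matrix(-2), b1 = -1, W2 = matrix(3),
              b2 = 0.5)
  expect_equal(as.numeric(out2), c(0.5, 0.5))
  # identical positions map to identical outputs
  set.seed(12)
  W1 <- matrix(rnorm(8), 2); b1 <- rnorm(4)
  W2 <- matrix(rnorm(8), 4); b2 <- rnorm(2)
  X <- rbind(c(1, 2), c(1, 2), c(0, 1))
  out3 <- ffn(X, W1, b1, W2, b2)
  expect_identical(out3[1, ], out3[2, ])
})

test_that("encoder layers normalize, pass residuals, and stack", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 2)
  ly <- m$params$layers[[1]]
  set.seed(3)
  X <- matrix(rnorm(10 * cfg$d_model, sd = 2), 10)

  # zero-weight sublayers: output is LayerNorm(X)
  ly0 <- ly
  for (nm in c("Wq", "Wk", "Wv", "Wo", "bo", "W1", "b1", "W2", "b2"))
    ly0[[nm]][] <- 0
  expect_equal(encoder_layer(X, ly0, cfg), layer_norm(X), tolerance = 1e-5)

  # pre-gain normalization: per-position mean 0, variance 1
  Xn <- layer_norm(X)
  expect_lt(max(abs(rowMeans(Xn))), 1e-10)
  expect_lt(max(abs(rowMeans(Xn^2) - 1)), 1e-4)

  # width preserved through a full layer
  out <- encoder_layer(X, ly, cfg)
  expect_identical(dim(out), dim(X))

  # an n-layer model applies the layer map n times: composing the
  # single-layer map manually reproduces the stacked forward pass
  cfg3 <- tiny_config(n_layers = 3L)
  m3 <- init_model(cfg3, seed = 9)
  x <- stats::rnorm(cfg3$window_len)
  E <- embed_window(m3, x)
  H <- E
  for (l in 1:3) H <- encoder_layer(H, m3$params$layers[[l]], cfg3)
  pooled <- colMeans(H)
  U <- pmax(pooled %*% m3$params$Wh1 + m3$params$bh1, 0)
  logits <- as.numeric(U %*% m3$params$Wh2 + m3$params$bh2)
  wp <- classify_window(m3, x)
  expect_equal(wp$logits, logits, tolerance = 1e-4)
  expect_equal(unname(wp$probs), as.numeric(softmax(logits)),
               tolerance = 1e-4)
})

test_that("classification head follows softmax identities", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  expect_equal(softmax(c(log(2), 0, 0, 0, 0)),
               c(2 / 6, 1 / 6, 1 / 6, 1 / 6, 1 / 6), tolerance = 1e-12)
  z <- c(0.3, -1, 2, 0.5, 0)
  expect_equal(softmax(z + 17.5), softmax(z), tolerance = 1e-12)

  cfg <- tiny_config()
  m <- init_model(cfg, seed = 77)
  set.seed(5)
  for (i in 1:10) {
    wp <- classify_window(m, rnorm(cfg$window_len))
    expect_true(all(wp$probs >= 0))
    expect_lt(abs(sum(wp$probs) - 1), 1e-6)
  }
  # inference is deterministic with dropout disabled
  x <- rnorm(cfg$window_len)
  expect_identical(classify_window(m, x)$probs, classify_window(m, x)$probs)
})

test_that("parameter count matches a hand-tallied ledger and closed forms", {
  cfg <- model_config(d_model = 4, n_layers = 1, n_heads = 1, key_dim = 4,
                      ffn_dim = 8, dropout = 0, t2v_k = 2, window_len = 20,
                      n_classes = 5, head_hidden = 4)
  m <- init_model(cfg, 1)
  # hand tally: t2v 3+3; w_sig 4; b_emb 4; W_t2v 3*4;
  # per layer: 3*(4*4+4) QKV, 4*4+4 Wo, 2*(4+4) layer norms,
  #            4*8+8 W1/b1, 8*4+4 W2/b2; head: 4*4+4 + 4*5+5
  hand <- (3 + 3) + 4 + 4 + 12 +
    (3 * (16 + 4) + (16 + 4) + 2 * 8 + (32 + 8) + (32 + 4)) +
    (16 + 4) + (20 + 5)
  expect_identical(count_parameters(m), as.integer(hand))

  # doubling ffn_dim adds exactly n_layers * (2*d_model*ffn_dim + ffn_dim)
  cfg2 <- model_config(d_model = 4, n_layers = 2, n_heads = 1, key_dim = 4,
                       ffn_dim = 8, t2v_k = 2, window_len = 20,
                       head_hidden = 4)
  cfg2b <- model_config(d_model = 4, n_layers = 2, n_heads = 1, key_dim = 4,
                        ffn_dim = 16, t2v_k = 2, window_len = 20,
                        head_hidden = 4)
  expect_identical(count_parameters(init_model(cfg2b, 1)) -
                     count_parameters(init_model(cfg2, 1)),
                   2L * (2L * 4L * 8L + 8L))

  # a zero-layer encoder counts embedding plus head parameters only
  cfg0 <- model_config(d_model = 4, n_layers = 0, n_heads = 1, key_dim = 4,
                       ffn_dim = 8, t2v_k = 2, window_len = 20,
                       head_hidden = 4)
  expect_identical(count_parameters(init_model(cfg0, 1)),
                   as.integer((3 + 3) + 4 + 4 + 12 + (16 + 4) + (20 + 5)))
})

test_that("one optimization step decreases training cross-entropy", {
  cfg <- tiny_config(dropout = 0)
  set.seed(64)
  for (seed in c(1, 2, 3)) {
    m <- init_model(cfg, seed = seed)
    Xw <- matrix(rnorm(16 * cfg$window_len), 16)
    y <- rep(1:4, each = 4)
    st <- ecgrhythm:::adam_init(m$params)
    fw <- ecgrhythm:::forward_batch(m, Xw, training = TRUE, keep = TRUE)
    bw <- ecgrhythm:::backward_batch(m, fw$cache, y)
    up <- ecgrhythm:::adam_step(m$params, bw$grads, st, lr = 1e-2, l2 = 0)
    m$params <- up$params
    fw2 <- ecgrhythm:::forward_batch(m, Xw)
    loss2 <- -mean(log(fw2$probs[cbind(seq_along(y), y)]))
    expect_lt(loss2, bw$loss)
  }
})

test_that("fast single-precision path agrees with the double reference path", {
  cfg <- tiny_config(n_layers = 2L, window_len = 30L, d_model = 16L,
                     key_dim = 8L, ffn_dim = 24L)
  m <- init_model(cfg, seed = 4)
  set.seed(9)
  Xw <- matrix(rnorm(5 * 30), 5)
  y <- 1:5
  fast_fw <- ecgrhythm:::forward_batch(m, Xw, keep = TRUE)
  fast_bw <- ecgrhythm:::backward_batch(m, fast_fw$cache, y)
  ref <- withr::with_options(list(ecgrhythm.attn_double = TRUE), {
    fw <- ecgrhythm:::forward_batch(m, Xw, keep = TRUE)
    list(fw = fw, bw = ecgrhythm:::backward_batch(m, fw$cache, y))
  })
  expect_equal(fast_fw$probs, ref$fw$probs, tolerance = 1e-5)
  expect_equal(fast_bw$loss, ref$bw$loss, tolerance = 1e-5)
  for (lf in c("Wq", "Wo", "W1", "W2", "ln1_g", "bv"))
    for (l in 1:2)
      expect_equal(fast_bw$grads$layers[[l]][[lf]],
                   ref$bw$grads$layers[[l]][[lf]], tolerance = 1e-4,
                   ignore_attr = TRUE)
  expect_equal(fast_bw$grads$w_sig, ref$bw$grads$w_sig, tolerance = 1e-4)
})

test_that("backward pass matches finite-difference gradients", {
  withr::local_options(ecgrhythm.attn_double = TRUE)
  cfg <- tiny_config(n_layers = 2L, window_len = 12L)
  m <- init_model(cfg, seed = 3)
  set.seed(42)
  Xw <- matrix(rnorm(3 * 12), 3, 12)
  y <- c(1L, 3L, 5L)
  fb <- ecgrhythm:::forward_batch(m, Xw, keep = TRUE)
  bw <- ecgrhythm:::backward_batch(m, fb$cache, y)
  lossfun <- function(model) {
    p <- ecgrhythm:::forward_batch(model, Xw)$probs
    -mean(log(p[cbind(1:3, y)]))
  }
  eps <- 1e-6
  leaves <- list(list(NULL, "t2v_omega"), list(NULL, "w_sig"),
                 list(NULL, "W_t2v"), list(1L, "Wq"), list(1L, "Wo"),
                 list(2L, "Wv"), list(1L, "ln1_g"), list(2L, "W1"),
                 list(2L, "ln2_b"), list(NULL, "Wh1"), list(NULL, "bh2"))
  for (lf in leaves) {
    for (idx in 1:2) {
      pert <- function(mm, dlt) {
        if (is.null(lf[[1]])) {
          mm$params[[lf[[2]]]][idx] <- mm$params[[lf[[2]]]][idx] + dlt
        } else {
          mm$params$layers[[lf[[1]]]][[lf[[2]]]][idx] <-
            mm$params$layers[[lf[[1]]]][[lf[[2]]]][idx] + dlt
        }
        mm
      }
      num <- (lossfun(pert(m, eps)) - lossfun(pert(m, -eps))) / (2 * eps)
      ana <- if (is.null(lf[[1]])) bw$grads[[lf[[2]]]][idx]
             else bw$grads$layers[[lf[[1]]]][[lf[[2]]]][idx]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-7), 1e-3)
    }
  }
})
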