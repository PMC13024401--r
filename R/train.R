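# Backpropagation through the batched forward pass. Attention softmax
# weights are recomputed from the cached Q/K rather than stored (memory for
# flops trade: a 250x250 weight matrix per window per head dominates the
# cache otherwise).

ln_backward <- function(dout, xhat, inv, gamma) {
  dxhat <- dout * matrix(gamma, nrow(dout), ncol(dout), byrow = TRUE)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       dgamma = colSums(dout * xhat),
       dbeta = colSums(dout))
}

backward_batch <- function(model, cache, y) {
  cfg <- model$cfg; p <- model$params
  B <- cache$B; W <- cache$W; N <- B * W
  d <- cfg$d_model; hd <- cfg$n_heads * cfg$key_dim
  probs <- cache$probs

  g <- list()
  dZ <- probs
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  g$Wh2 <- crossprod(cache$Ud, dZ)
  g$bh2 <- colSums(dZ)
  dUd <- tcrossprod(dZ, p$Wh2)
  dU <- if (!is.null(cache$dmu)) dUd * cache$dmu else dUd
  dUpre <- dU * (cache$U > 0)
  g$Wh1 <- crossprod(cache$P, dUpre)
  g$bh1 <- colSums(dUpre)
  dP <- tcrossprod(dUpre, p$Wh1)

  dX <- switch(cfg$pooling,
               mean = dP[rep(seq_len(B), each = W), , drop = FALSE] / W,
               last = {
                 m <- matrix(0, N, d)
                 m[seq_len(B) * W, ] <- dP
                 m
               },
               cls = {
                 m <- matrix(0, N, d)
                 m[(seq_len(B) - 1L) * W + 1L, ] <- dP
                 m
               })

  g$layers <- vector("list", cfg$n_layers)
  if (!is.null(cache$enc_ptr)) {
    encb <- .encoder_backward_cpp(dX, p$layers, cache$enc_ptr, B, W,
                                  cfg$n_heads, cfg$key_dim)
    g$layers <- encb$grads
    dX <- encb$dX0
  } else for (l in rev(seq_len(cfg$n_layers))) {
    ly <- p$layers[[l]]; cc <- cache$layers[[l]]
    gl <- list()
    ln2 <- ln_backward(dX, cc$xhat2, cc$inv2, ly$ln2_g)
    gl$ln2_g <- ln2$dgamma; gl$ln2_b <- ln2$dbeta
    dR2 <- ln2$dx
    dFo <- if (!is.null(cc$dm2)) dR2 * cc$dm2 else dR2
    gl$W2 <- crossprod(cc$H, dFo)
    gl$b2 <- colSums(dFo)
    dH <- tcrossprod(dFo, ly$W2)
    dHpre <- dH * (cc$H > 0)
    gl$W1 <- crossprod(cc$X1, dHpre)
    gl$b1 <- colSums(dHpre)
    dX1 <- dR2 + tcrossprod(dHpre, ly$W1)
    ln1 <- ln_backward(dX1, cc$xhat1, cc$inv1, ly$ln1_g)
    gl$ln1_g <- ln1$dgamma; gl$ln1_b <- ln1$dbeta
    dR1 <- ln1$dx
    dM <- if (!is.null(cc$dm1)) dR1 * cc$dm1 else dR1
    gl$Wo <- crossprod(cc$O, dM)
    gl$bo <- colSums(dM)
    dO <- tcrossprod(dM, ly$Wo)
    datt <- .attn_backward_cpp(cc$Q, cc$K, cc$V, dO, B, W, cfg$n_heads,
                               cfg$key_dim, attn_single_precision())
    dQ <- datt$dQ; dK <- datt$dK; dV <- datt$dV
    X0 <- cc$X0
    gl$Wq <- crossprod(X0, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(X0, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(X0, dV); gl$bv <- colSums(dV)
    dX <- dR1 + tcrossprod(dQ, ly$Wq) + tcrossprod(dK, ly$Wk) +
      tcrossprod(dV, ly$Wv)
    g$layers[[l]] <- gl
  }

  g$b_emb <- colSums(dX)
  g$w_sig <- as.numeric(crossprod(dX, cache$s))
  dE_time <- rowsum(dX, rep(seq_len(W), B), reorder = FALSE)  # W x d
  g$W_t2v <- cache$T2V %*% dE_time
  dT2Vt <- tcrossprod(dE_time, p$W_t2v)  # W x (k+1)
  tau <- seq_len(W) - 1
  k1 <- cfg$t2v_k + 1L
  g$t2v_omega <- numeric(k1); g$t2v_phi <- numeric(k1)
  g$t2v_omega[1] <- sum(dT2Vt[, 1] * tau)
  g$t2v_phi[1] <- sum(dT2Vt[, 1])
  for (i in 2:k1) {
    carg <- cos(p$t2v_omega[i] * tau + p$t2v_phi[i])
    g$t2v_omega[i] <- sum(dT2Vt[, i] * carg * tau)
    g$t2v_phi[i] <- sum(dT2Vt[, i] * carg)
  }

  loss <- -mean(log(pmax(probs[cbind(seq_len(B), y)], 1e-12)))
  list(grads = g, loss = loss)
}

# L2 weight decay targets: weight matrices only (no biases, layer norms, or
# Time2Vec frequencies/phases).
.decay_leaves <- c("w_sig", "W_t2v", "Wq", "Wk", "Wv", "Wo", "W1", "W2",
                   "Wh1", "Wh2")

# Learning rate at optimizer step t: linear warmup, then constant or a half
# cosine decaying to 10% of the peak by the final planned step.
scheduled_lr <- function(control, t, total_steps) {
  lr <- control$lr
  if (control$warmup_steps > 0) lr <- lr * min(1, t / control$warmup_steps)
  if (identical(control$lr_schedule %||% "constant", "cosine")) {
    frac <- min(1, t / max(total_steps, 1))
    lr <- lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * frac)))
  }
  lr
}

# Scale all gradients so their global L2 norm is at most `max_norm`.
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  sq <- function(x) if (is.list(x)) sum(vapply(x, sq, numeric(1)))
                    else sum(x * x)
  total <- sqrt(sq(grads))
  if (total <= max_norm) return(grads)
  scale_by <- max_norm / total
  walk <- function(x) if (is.list(x)) lapply(x, walk) else x * scale_by
  walk(grads)
}

adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, l2, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(w, g, m, v, name) {
    if (is.list(w)) {
      out <- list(w = w, m = m, v = v)
      for (nm in names(w)) {
        r <- walk(w[[nm]], g[[nm]], m[[nm]], v[[nm]], nm)
        out$w[[nm]] <- r$w; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      if (is.null(names(w))) {  # layers list
        for (i in seq_along(w)) {
          r <- walk(w[[i]], g[[i]], m[[i]], v[[i]], "")
          out$w[[i]] <- r$w; out$m[[i]] <- r$m; out$v[[i]] <- r$v
        }
      }
      out
    } else {
      if (l2 > 0 && name %in% .decay_leaves) g <- g + l2 * w
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(w = w, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v, "")
  list(params = r$w, state = list(m = r$m, v = r$v, t = state$t))
}

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param batch_size windows per optimization step.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param stride sliding-window stride (samples) used for training windows
#'   and later prediction.
#' @param windows_per_record windows sampled per recording per epoch
#'   (`NULL` = all windows every epoch). Subsampling revisits different
#'   windows each epoch while bounding epoch cost.
#' @param val_windows_per_record evenly spaced windows per validation
#'   recording used for the per-epoch validation loss/accuracy.
#' @param warmup_steps linear learning-rate warmup horizon in optimizer
#'   steps (0 disables warmup). Transformers are prone to early attention
#'   collapse at full learning rate; a short warmup stabilizes the first
#'   epoch.
#' @param clip_norm global gradient-norm clipping threshold (Inf disables).
#'   Together with warmup this prevents the rare collapse of a freshly
#'   initialized encoder to uniform predictions.
#' @param lr_schedule `"constant"` keeps the post-warmup rate fixed;
#'   `"cosine"` decays it along a half cosine to 10% of the peak by the
#'   final planned step, which settles the decision boundary in the last
#'   epochs instead of bouncing around it.
#' @param seed integer seed controlling initialization order, window
#'   sampling, and dropout.
#' @param verbose print per-epoch progress.
#' @return object of class `train_control`.
#' @export
train_control <- function(lr = 1e-3, batch_size = 64L, max_epochs = 30L,
                          patience = 5L, stride = 5L,
                          windows_per_record = NULL,
                          val_windows_per_record = 8L, warmup_steps = 30L,
                          clip_norm = 1,
                          lr_schedule = c("constant", "cosine"),
                          seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), stride = as.integer(stride),
                 windows_per_record = windows_per_record,
                 val_windows_per_record = as.integer(val_windows_per_record),
                 warmup_steps = as.integer(warmup_steps),
                 clip_norm = clip_norm, lr_schedule = lr_schedule,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

# Standardize labeled records and cut training windows.
assemble_windows <- function(records, W, S, duration_s = 10) {
  if (length(records) == 0)
    stop("configuration error: empty partition", call. = FALSE)
  labs <- vapply(records, function(r) {
    if (is.null(r$label)) stop("all records must be labeled", call. = FALSE)
    r$label
  }, character(1))
  assert_rhythm_label(labs)
  per <- lapply(records, function(r) {
    slide_windows(standardize_record(r, duration_s = duration_s), W = W,
                  S = S)$windows
  })
  n_per <- vapply(per, nrow, integer(1))
  list(windows = do.call(rbind, per),
       y = rep(match(labs, RHYTHM_CLASSES), times = n_per),
       record = rep(seq_along(records), times = n_per),
       n_per = n_per, labels = labs)
}

#' Train the rhythm classifier
#'
#' Fits the Time2Vec-transformer window classifier with Adam on categorical
#' cross-entropy over window labels (inherited from the parent recording).
#' L2 regularization from the model configuration is applied as weight decay
#' on the weight matrices. Early stopping monitors window-level validation
#' loss with the configured patience and restores the best parameters;
#' recording-level validation accuracy (majority vote over the validation
#' window subset) is logged per epoch.
#'
#' @param train_records list of labeled [ecg_record()]s.
#' @param model_cfg a [model_config()].
#' @param control a [train_control()].
#' @param val_records optional list of labeled records for validation/early
#'   stopping.
#' @return object of class `rhythm_fit`: list with `model`, `history`
#'   (data.frame of epoch, train_loss, val_loss, val_acc), `control`,
#'   `n_params`, `best_epoch`.
#' @export
fit_rhythm_model <- function(train_records, model_cfg = model_config(),
                             control = train_control(),
                             val_records = NULL) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(control, "train_control"))
  tr <- assemble_windows(train_records, model_cfg$window_len, control$stride)
  va <- if (!is.null(val_records) && length(val_records) > 0) {
    assemble_windows(val_records, model_cfg$window_len, control$stride)
  } else NULL

  with_seed(combine_seeds(control$seed, 12582917L), {
    model <- init_model(model_cfg, seed = control$seed)
    state <- adam_init(model$params)

    # fixed validation window subset (evenly spaced within each recording)
    val_idx <- NULL
    if (!is.null(va)) {
      val_idx <- unlist(lapply(seq_along(va$n_per), function(r) {
        rows <- which(va$record == r)
        k <- min(control$val_windows_per_record, length(rows))
        rows[unique(round(seq(1, length(rows), length.out = k)))]
      }))
    }

    steps_per_epoch <- ceiling(sum(pmin(control$windows_per_record %||%
                                          max(tr$n_per), tr$n_per)) /
                                 control$batch_size)
    total_steps <- steps_per_epoch * control$max_epochs

    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), val_acc = numeric())
    best_loss <- Inf; best_params <- model$params; best_epoch <- 0L
    bad_epochs <- 0L
    n_rec <- length(tr$n_per)

    for (epoch in seq_len(control$max_epochs)) {
      use <- if (is.null(control$windows_per_record)) {
        seq_len(nrow(tr$windows))
      } else {
        unlist(lapply(seq_len(n_rec), function(r) {
          rows <- which(tr$record == r)
          sample(rows, min(control$windows_per_record, length(rows)))
        }))
      }
      use <- use[sample.int(length(use))]
      losses <- numeric(0)
      i <- 1L
      while (i <= length(use)) {
        j <- min(i + control$batch_size - 1L, length(use))
        rows <- use[i:j]
        fw <- forward_batch(model, tr$windows[rows, , drop = FALSE],
                            training = TRUE, keep = TRUE)
        bw <- backward_batch(model, fw$cache, tr$y[rows])
        lr_t <- scheduled_lr(control, state$t + 1, total_steps)
        grads <- clip_global_norm(bw$grads, control$clip_norm)
        up <- adam_step(model$params, grads, state, lr_t, model_cfg$l2)
        model$params <- up$params
        state <- up$state
        losses <- c(losses, bw$loss)
        i <- j + 1L
      }
      train_loss <- mean(losses)

      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(va)) {
        vp <- classify_windows(model, va$windows[val_idx, , drop = FALSE])
        vy <- va$y[val_idx]
        val_loss <- -mean(log(pmax(vp[cbind(seq_along(vy), vy)], 1e-12)))
        vrec <- va$record[val_idx]
        pred_lab <- vapply(unique(vrec), function(r) {
          majority_vote(vp[vrec == r, , drop = FALSE])$label
        }, character(1))
        val_acc <- mean(pred_lab == va$labels[unique(vrec)])
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss,
                                           val_acc = val_acc))
      if (control$verbose)
        message(sprintf("epoch %d: train %.4f val %.4f acc %.3f", epoch,
                        train_loss, val_loss, val_acc))
      monitor <- if (!is.null(va)) val_loss else train_loss
      if (monitor < best_loss - 1e-6) {
        best_loss <- monitor
        best_params <- model$params
        best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= control$patience) break
      }
    }
    model$params <- best_params
    structure(list(model = model, history = history, control = control,
                   n_params = count_parameters(model),
                   best_epoch = best_epoch),
              class = "rhythm_fit")
  })
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf("<rhythm_fit> %d epochs (best %d), %s parameters\n",
              nrow(x$history), x$best_epoch,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Save a trained model
#'
#' Writes the weights (`weights.rds`) and a JSON model card
#' (`model_card.json`) recording the configuration, exact parameter count,
#' seed, and training history.
#'
#' @param fit a [fit_rhythm_model()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
save_rhythm_model <- function(fit, dir) {
  stopifnot(inherits(fit, "rhythm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(fit$model$params, file.path(dir, "weights.rds"))
  card <- list(config = unclass(fit$model$cfg),
               n_params = fit$n_params,
               seed = fit$model$seed,
               control = unclass(fit$control),
               best_epoch = fit$best_epoch,
               history = fit$history)
  jsonlite::write_json(card, file.path(dir, "model_card.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a trained model
#'
#' @param dir directory written by [save_rhythm_model()].
#' @return a `rhythm_fit`.
#' @export
load_rhythm_model <- function(dir) {
  card <- jsonlite::read_json(file.path(dir, "model_card.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, card$config[setdiff(names(card$config), NULL)])
  params <- readRDS(file.path(dir, "weights.rds"))
  model <- structure(list(cfg = cfg, params = params,
                          seed = as.integer(card$seed)),
                     class = "rhythm_model")
  ctl <- do.call(train_control, card$control)
  structure(list(model = model,
                 history = as.data.frame(card$history),
                 control = ctl,
                 n_params = card$n_params,
                 best_epoch = card$best_epoch),
            class = "rhythm_fit")
}
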