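#' Encoder configuration
#'
#' Architecture of the k-mer transformer-encoder classifier. The full-scale
#' nucleotide-BERT geometry is 12 layers x 12 heads x 768 hidden; the default
#' here is the desk-scale 2 x 2 x 32 configuration used throughout the test
#' suite, which trains in seconds on one CPU.
#'
#' @param n_layers number of transformer encoder layers.
#' @param n_heads self-attention heads per layer; must divide `hidden_size`.
#' @param hidden_size token embedding / hidden dimension.
#' @param k k-mer size of the tokenizer feeding the model.
#' @param max_tokens maximum token count (L + 2) accepted per sequence.
#' @param ff_mult feed-forward inner dimension as a multiple of `hidden_size`.
#' @param dropout dropout fraction applied during training (0 disables).
#' @param seed seed for weight initialization.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 2L, n_heads = 2L, hidden_size = 32L,
                           k = 3L, max_tokens = 128L, ff_mult = 4L,
                           dropout = 0, seed = 1L) {
  if (hidden_size %% n_heads != 0L)
    stop("hidden_size must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_size = as.integer(hidden_size),
                 k = as.integer(k), max_tokens = as.integer(max_tokens),
                 ff_mult = as.integer(ff_mult), dropout = dropout,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Training settings
#'
#' Optimization hyperparameters for [train_classifier()]. The published
#' fine-tuning hyperparameters of the reference nucleotide-BERT models are
#' not part of this package; these defaults follow standard transformer
#' fine-tuning practice (Adam, small learning rate, linear warmup then linear
#' decay) and are recorded in every trained provider.
#'
#' @param learning_rate peak Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs passes over the training set.
#' @param weight_decay decoupled weight decay applied to weight matrices.
#' @param warmup_fraction fraction of total steps spent linearly warming up.
#' @param seed seed for shuffling and dropout.
#' @return a `training_settings` list.
#' @export
training_settings <- function(learning_rate = 2e-3, batch_size = 32L,
                              epochs = 4L, weight_decay = 0.01,
                              warmup_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size > 0, epochs >= 0,
            weight_decay >= 0, warmup_fraction >= 0, warmup_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 warmup_fraction = warmup_fraction, seed = as.integer(seed)),
            class = "training_settings")
}

# ---- parameter initialization -------------------------------------------

layer_param_names <- function(i) {
  paste0("l", i, "_", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                        "ln1_g", "ln1_b", "W1", "b1", "W2", "b2",
                        "ln2_g", "ln2_b"))
}

init_params <- function(config, vocab_size) {
  local_rng(config$seed)
  d <- config$hidden_size
  f <- d * config$ff_mult
  sd0 <- 0.02
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sd0), nr, nc)
  p <- list(
    E = rn(vocab_size, d),
    P = rn(config$max_tokens, d),
    ln0_g = rep(1, d), ln0_b = rep(0, d))
  for (i in seq_len(config$n_layers)) {
    lp <- list(rn(d, d), rep(0, d), rn(d, d), rep(0, d), rn(d, d), rep(0, d),
               rn(d, d), rep(0, d), rep(1, d), rep(0, d),
               rn(d, f), rep(0, f), rn(f, d), rep(0, d), rep(1, d), rep(0, d))
    names(lp) <- layer_param_names(i)
    p <- c(p, lp)
  }
  p$Wp <- rn(d, d); p$bp <- rep(0, d)
  p$cls_w <- stats::rnorm(d, sd = sd0); p$cls_b <- 0
  p
}

# ---- primitive layers ----------------------------------------------------

ln_eps <- 1e-12

layer_norm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sigma <- sqrt(rowMeans(xc * xc) + ln_eps)
  xhat <- xc / sigma
  list(y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, sigma = sigma)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2L, g, "*")
  dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) / cache$sigma
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- forward / backward per sequence ------------------------------------

# ids: 0-based token ids (CLS ... SEP). Returns prediction, attention and,
# when `cache = TRUE`, all intermediates needed by backward_seq().
forward_seq <- function(params, config, ids, cache = FALSE,
                        keep_attention = FALSE, drop_mask = NULL) {
  T_ <- length(ids)
  d <- config$hidden_size
  nh <- config$n_heads
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  X <- params$E[ids + 1L, , drop = FALSE] + params$P[seq_len(T_), , drop = FALSE]
  ln0 <- layer_norm_fwd(X, params$ln0_g, params$ln0_b)
  X <- ln0$y
  caches <- vector("list", config$n_layers)
  attn <- if (keep_attention)
    array(NA_real_, c(config$n_layers, nh, T_, T_)) else NULL
  for (i in seq_len(config$n_layers)) {
    nm <- function(s) params[[paste0("l", i, "_", s)]]
    Q <- X %*% nm("Wq") + rep(nm("bq"), each = T_)
    K <- X %*% nm("Wk") + rep(nm("bk"), each = T_)
    V <- X %*% nm("Wv") + rep(nm("bv"), each = T_)
    O <- matrix(0, T_, d)
    A_list <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) * scale)
      A_list[[h]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      if (keep_attention) attn[i, h, , ] <- A
    }
    M <- O %*% nm("Wo") + rep(nm("bo"), each = T_)
    dm1 <- NULL
    if (!is.null(drop_mask)) { dm1 <- drop_mask[[i]]$attn; M <- M * dm1 }
    ln1 <- layer_norm_fwd(X + M, nm("ln1_g"), nm("ln1_b"))
    X1 <- ln1$y
    Hpre <- X1 %*% nm("W1") + rep(nm("b1"), each = T_)
    Hrelu <- pmax(Hpre, 0)
    Ff <- Hrelu %*% nm("W2") + rep(nm("b2"), each = T_)
    dm2 <- NULL
    if (!is.null(drop_mask)) { dm2 <- drop_mask[[i]]$ffn; Ff <- Ff * dm2 }
    ln2 <- layer_norm_fwd(X1 + Ff, nm("ln2_g"), nm("ln2_b"))
    if (cache)
      caches[[i]] <- list(X_in = if (i == 1L) ln0$y else caches[[i - 1L]]$X_out,
                          Q = Q, K = K, V = V, A = A_list, O = O,
                          ln1 = ln1, X1 = X1, Hrelu = Hrelu,
                          ln2 = ln2, X_out = ln2$y, dm1 = dm1, dm2 = dm2)
    X <- ln2$y
  }
  cvec <- X[1L, ]
  u <- drop(cvec %*% params$Wp) + params$bp
  tpool <- tanh(u)
  logit <- sum(tpool * params$cls_w) + params$cls_b
  p <- 1 / (1 + exp(-logit))
  list(p = p, logit = logit, attn = attn,
       cache = if (cache) list(ids = ids, T_ = T_, ln0 = ln0,
                               layers = caches, cvec = cvec, tpool = tpool,
                               X_final = X) else NULL)
}

# Backpropagate dL/dlogit through the cached forward pass; returns the
# gradient as a flat list parallel to params.
backward_seq <- function(params, config, fwd, dlogit) {
  cache <- fwd$cache
  T_ <- cache$T_
  d <- config$hidden_size
  nh <- config$n_heads
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  g <- list()
  # classifier head
  tpool <- cache$tpool
  g$cls_w <- dlogit * tpool
  g$cls_b <- dlogit
  du <- (dlogit * params$cls_w) * (1 - tpool^2)
  g$Wp <- outer(cache$cvec, du)
  g$bp <- du
  dX <- matrix(0, T_, d)
  dX[1L, ] <- drop(params$Wp %*% du)
  for (i in rev(seq_len(config$n_layers))) {
    nm <- function(s) params[[paste0("l", i, "_", s)]]
    gn <- function(s) paste0("l", i, "_", s)
    lc <- cache$layers[[i]]
    # LN2
    b2 <- layer_norm_bwd(dX, lc$ln2, nm("ln2_g"))
    g[[gn("ln2_g")]] <- b2$dg; g[[gn("ln2_b")]] <- b2$db
    dR2 <- b2$dx
    dFf <- dR2
    if (!is.null(lc$dm2)) dFf <- dFf * lc$dm2
    # FFN
    g[[gn("W2")]] <- t(lc$Hrelu) %*% dFf
    g[[gn("b2")]] <- colSums(dFf)
    dHrelu <- dFf %*% t(nm("W2"))
    dHpre <- dHrelu * (lc$Hrelu > 0)
    g[[gn("W1")]] <- t(lc$X1) %*% dHpre
    g[[gn("b1")]] <- colSums(dHpre)
    dX1 <- dR2 + dHpre %*% t(nm("W1"))
    # LN1
    b1 <- layer_norm_bwd(dX1, lc$ln1, nm("ln1_g"))
    g[[gn("ln1_g")]] <- b1$dg; g[[gn("ln1_b")]] <- b1$db
    dR1 <- b1$dx
    dM <- dR1
    if (!is.null(lc$dm1)) dM <- dM * lc$dm1
    # output projection
    g[[gn("Wo")]] <- t(lc$O) %*% dM
    g[[gn("bo")]] <- colSums(dM)
    dO <- dM %*% t(nm("Wo"))
    dQ <- matrix(0, T_, d); dK <- matrix(0, T_, d); dV <- matrix(0, T_, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- lc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- lc$V[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, cols] <- t(A) %*% dOh
      dZ <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dZ %*% lc$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- (t(dZ) %*% lc$Q[, cols, drop = FALSE]) * scale
    }
    Xin <- lc$X_in
    g[[gn("Wq")]] <- t(Xin) %*% dQ; g[[gn("bq")]] <- colSums(dQ)
    g[[gn("Wk")]] <- t(Xin) %*% dK; g[[gn("bk")]] <- colSums(dK)
    g[[gn("Wv")]] <- t(Xin) %*% dV; g[[gn("bv")]] <- colSums(dV)
    dX <- dR1 + dQ %*% t(nm("Wq")) + dK %*% t(nm("Wk")) + dV %*% t(nm("Wv"))
  }
  # embedding layer norm
  b0 <- layer_norm_bwd(dX, cache$ln0, params$ln0_g)
  g$ln0_g <- b0$dg; g$ln0_b <- b0$db
  dX0 <- b0$dx
  # positional + token embeddings (accumulate duplicate ids)
  dP <- matrix(0, nrow(params$P), d)
  dP[seq_len(T_), ] <- dX0
  g$P <- dP
  dE <- matrix(0, nrow(params$E), d)
  acc <- rowsum(dX0, group = cache$ids)
  dE[as.integer(rownames(acc)) + 1L, ] <- acc
  g$E <- dE
  g
}

# ---- provider object -----------------------------------------------------

new_provider <- function(params, config, vocab, settings = NULL,
                         history = NULL) {
  structure(list(params = params, config = config, vocab = vocab,
                 settings = settings, history = history),
            class = "rbp_provider")
}

#' @export
print.rbp_provider <- function(x, ...) {
  cat(sprintf("<rbp_provider> %d layers x %d heads, hidden %d, k=%d\n",
              x$config$n_layers, x$config$n_heads, x$config$hidden_size,
              x$config$k))
  if (!is.null(x$history))
    cat(sprintf("  trained %d steps; final eval loss %.4f\n",
                x$history$steps, utils::tail(x$history$eval_loss, 1L)))
  invisible(x)
}

#' Initialize an untrained provider
#'
#' Random initialization (the "baseline" condition); pass the result as
#' `initial_weights` to [train_classifier()] or use it directly to sample
#' attention from an untrained encoder.
#'
#' @param config an [encoder_config()].
#' @param vocab a [build_vocabulary()] result with matching `k`.
#' @return an `rbp_provider`.
#' @export
init_provider <- function(config, vocab) {
  stopifnot(inherits(config, "encoder_config"), inherits(vocab, "kmer_vocab"))
  if (config$k != vocab$k) stop("config k and vocabulary k differ")
  new_provider(init_params(config, length(vocab$tokens)), config, vocab)
}

check_batch <- function(provider, tokenized) {
  lens <- vapply(tokenized, function(t) length(t$token_ids), integer(1))
  if (any(lens > provider$config$max_tokens))
    stop("input exceeds max_tokens = ", provider$config$max_tokens)
  invisible(lens)
}

#' Train the encoder classifier
#'
#' Fine-tunes (or trains from scratch) the transformer-encoder binary
#' classifier: the final-layer CLS vector feeds a tanh pooler and a logistic
#' classification head; the loss is binary cross-entropy, optimized with Adam
#' under linear warmup / linear decay. Deterministic for fixed data, config
#' and seeds on a single device.
#'
#' @param train_tok list of `tokenized_seq` for training.
#' @param train_labels 0/1 (or logical) labels aligned with `train_tok`.
#' @param eval_tok,eval_labels held-out evaluation set, used only to record
#'   the eval loss per epoch.
#' @param config an [encoder_config()].
#' @param settings a [training_settings()].
#' @param initial_weights optional `rbp_provider` (or checkpoint loaded with
#'   [load_checkpoint()]) whose embedding and encoder parameters initialize
#'   the model; shapes must match `config`. When absent, weights are random
#'   (the baseline condition).
#' @return a trained `rbp_provider` with a `history` element (per-epoch train
#'   and eval loss).
#' @export
train_classifier <- function(train_tok, train_labels, eval_tok = NULL,
                             eval_labels = NULL, config = encoder_config(),
                             settings = training_settings(),
                             initial_weights = NULL) {
  if (length(train_tok) == 0L) stop("empty training set")
  y <- as.numeric(train_labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  vocab <- build_vocabulary(config$k)
  if (is.null(initial_weights)) {
    params <- init_params(config, length(vocab$tokens))
  } else {
    src <- if (inherits(initial_weights, "rbp_provider"))
      initial_weights$params else initial_weights
    params <- init_params(config, length(vocab$tokens))
    for (nm in names(params)) {
      if (!nm %in% names(src))
        stop("checkpoint is missing parameter ", nm)
      if (!identical(dim_or_len(src[[nm]]), dim_or_len(params[[nm]])))
        stop("checkpoint shape mismatch for parameter ", nm)
      params[[nm]] <- src[[nm]]
    }
  }
  provider <- new_provider(params, config, vocab, settings)
  check_batch(provider, train_tok)

  n <- length(train_tok)
  steps_per_epoch <- ceiling(n / settings$batch_size)
  total_steps <- steps_per_epoch * settings$epochs
  if (total_steps == 0L) {
    provider$history <- list(steps = 0L, train_loss = numeric(),
                             eval_loss = numeric())
    return(provider)
  }
  warmup <- max(1, floor(total_steps * settings$warmup_fraction))
  m <- lapply(params, function(x) x * 0)
  v <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  decay_names <- names(params)[vapply(params, is.matrix, logical(1))]
  local_rng(settings$seed)
  step <- 0L
  hist_train <- numeric(settings$epochs)
  hist_eval <- numeric(settings$epochs)
  ids_list <- lapply(train_tok, `[[`, "token_ids")
  for (epoch in seq_len(settings$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (bstart in seq(1L, n, by = settings$batch_size)) {
      idx <- ord[bstart:min(bstart + settings$batch_size - 1L, n)]
      gsum <- NULL
      bloss <- 0
      for (s in idx) {
        dm <- make_dropout_masks(config, length(ids_list[[s]]))
        fwd <- forward_seq(params, config, ids_list[[s]], cache = TRUE,
                           drop_mask = dm)
        p <- min(max(fwd$p, 1e-12), 1 - 1e-12)
        bloss <- bloss - (y[s] * log(p) + (1 - y[s]) * log(1 - p))
        gs <- backward_seq(params, config, fwd, dlogit = fwd$p - y[s])
        gsum <- if (is.null(gsum)) gs else
          mapply(`+`, gsum, gs[names(gsum)], SIMPLIFY = FALSE)
      }
      nb <- length(idx)
      step <- step + 1L
      lr_frac <- if (step <= warmup) step / warmup else
        (total_steps - step + 1) / max(1, total_steps - warmup)
      lr <- settings$learning_rate * lr_frac
      for (nm in names(params)) {
        gr <- gsum[[nm]] / nb
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr * gr
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        upd <- mhat / (sqrt(vhat) + eps)
        if (nm %in% decay_names)
          upd <- upd + settings$weight_decay * params[[nm]]
        params[[nm]] <- params[[nm]] - lr * upd
      }
      ep_loss <- ep_loss + bloss
    }
    hist_train[epoch] <- ep_loss / n
    hist_eval[epoch] <- if (!is.null(eval_tok) && length(eval_tok))
      mean_bce(params, config, eval_tok, as.numeric(eval_labels)) else NA_real_
  }
  provider$params <- params
  provider$history <- list(steps = step, train_loss = hist_train,
                           eval_loss = hist_eval)
  provider
}

dim_or_len <- function(x) if (is.matrix(x)) dim(x) else length(x)

make_dropout_masks <- function(config, T_) {
  if (config$dropout <= 0) return(NULL)
  keep <- 1 - config$dropout
  d <- config$hidden_size
  lapply(seq_len(config$n_layers), function(i) list(
    attn = matrix(stats::rbinom(T_ * d, 1L, keep) / keep, T_, d),
    ffn = matrix(stats::rbinom(T_ * d, 1L, keep) / keep, T_, d)))
}

mean_bce <- function(params, config, tok, y) {
  loss <- 0
  for (s in seq_along(tok)) {
    p <- forward_seq(params, config, tok[[s]]$token_ids)$p
    p <- min(max(p, 1e-12), 1 - 1e-12)
    loss <- loss - (y[s] * log(p) + (1 - y[s]) * log(1 - p))
  }
  loss / length(tok)
}

#' Evaluation-set loss of a provider
#'
#' Mean binary cross-entropy of `provider` on a labeled tokenized set.
#'
#' @param provider an `rbp_provider`.
#' @param tokenized list of `tokenized_seq`.
#' @param labels 0/1 labels.
#' @return mean BCE loss (scalar).
#' @export
evaluate_loss <- function(provider, tokenized, labels) {
  check_batch(provider, tokenized)
  mean_bce(provider$params, provider$config, tokenized, as.numeric(labels))
}

#' Predict binding probabilities
#'
#' @param provider an `rbp_provider`.
#' @param tokenized list of `tokenized_seq` (token count at most
#'   `max_tokens`).
#' @return numeric vector of positive-class probabilities in `[0, 1]`, in
#'   input order.
#' @export
predict_binding <- function(provider, tokenized) {
  check_batch(provider, tokenized)
  vapply(tokenized, function(ts)
    forward_seq(provider$params, provider$config, ts$token_ids)$p,
    numeric(1))
}

#' Extract attention tensors
#'
#' Runs the encoder in evaluation mode (no dropout) and returns, per
#' sequence, the full row-normalized attention tensor: a 4-d array indexed
#' `[layer, head, i, j]` where `alpha[i, j]` is the weight with which
#' upper-layer token i attends to lower-layer token j. Token axis order is
#' CLS, sequence tokens, SEP; every row sums to 1.
#'
#' @param provider an `rbp_provider`.
#' @param tokenized list of `tokenized_seq`.
#' @return list of arrays of shape `(n_layers, n_heads, L+2, L+2)`.
#' @export
extract_attention <- function(provider, tokenized) {
  check_batch(provider, tokenized)
  lapply(tokenized, function(ts)
    forward_seq(provider$params, provider$config, ts$token_ids,
                keep_attention = TRUE)$attn)
}

#' Area under the ROC curve
#'
#' Tie-corrected rank statistic: the probability that a random positive
#' outscores a random negative, counting ties as one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical / two-level) labels.
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(scores, labels) {
  y <- as.numeric(as.logical(as.numeric(labels)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load provider checkpoints
#'
#' Checkpoints are RDS files holding the flat parameter list, the
#' configuration and the vocabulary `k`. The parameter names (`E`, `P`,
#' `ln0_*`, `l<i>_Wq/bq/Wk/bk/Wv/bv/Wo/bo/ln1_*/W1/b1/W2/b2/ln2_*`, `Wp`,
#' `bp`, `cls_w`, `cls_b`) are the import contract for externally pretrained
#' encoder weights: map a foreign checkpoint onto these names/shapes and pass
#' it as `initial_weights` to [train_classifier()].
#'
#' @param provider an `rbp_provider`.
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly (save); an `rbp_provider` (load).
#' @export
save_checkpoint <- function(provider, path) {
  stopifnot(inherits(provider, "rbp_provider"))
  saveRDS(provider[c("params", "config", "settings", "history")], path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  vocab <- build_vocabulary(x$config$k)
  new_provider(x$params, x$config, vocab, x$settings, x$history)
}
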