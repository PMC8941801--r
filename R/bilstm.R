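#' Peephole LSTM cell and BiLSTM-CRF sequence labeler
#'
#' The recurrent cell implements the peephole LSTM equations
#' \deqn{i_t = \sigma(W_{xi} x_t + W_{hi} h_{t-1} + W_{ci} C_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf} x_t + W_{hf} h_{t-1} + W_{cf} C_{t-1} + b_f)}
#' \deqn{C_t = f_t C_{t-1} + i_t \tanh(W_{xC} x_t + W_{hC} h_{t-1} + b_C)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} C_t + b_o)}
#' \deqn{h_t = o_t \tanh(C_t)}
#' with full peephole matrices acting on the cell state (note the output
#' gate peeks at the current cell \eqn{C_t}). A standard (non-peephole)
#' cell is available by zero peephole weights with `peephole = FALSE`.
#' Character embeddings are randomly initialized and trained; a
#' bidirectional pass produces per-character context vectors which a
#' linear projection turns into CRF emission scores; the CRF output layer
#' supplies label-transition scores and a hard BIO mask at decode time, so
#' `I-X` never follows `O`.
#'
#' @name bilstm-crf
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize peephole LSTM parameters
#'
#' Weights are drawn uniformly from `[-r, r]` with `r = 1/sqrt(hidden)`
#' (uses the current RNG state); biases start at zero. With
#' `peephole = FALSE` the `W_ci`, `W_cf`, `W_co` matrices are fixed at
#' zero, giving the standard LSTM cell.
#'
#' @param input_size embedding dimension.
#' @param hidden_size hidden state dimension.
#' @param peephole use peephole connections (default `TRUE`).
#' @return named list of weight matrices `W_xi, W_hi, W_ci, W_xf, W_hf,
#'   W_cf, W_xC, W_hC, W_xo, W_ho, W_co` and bias vectors `b_i, b_f, b_C,
#'   b_o`.
#' @export
lstm_params <- function(input_size, hidden_size, peephole = TRUE) {
  r <- 1 / sqrt(hidden_size)
  m <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  z <- function(nr, nc) matrix(0, nr, nc)
  E <- input_size; H <- hidden_size
  p <- list(
    W_xi = m(E, H), W_hi = m(H, H), W_ci = if (peephole) m(H, H) else z(H, H),
    W_xf = m(E, H), W_hf = m(H, H), W_cf = if (peephole) m(H, H) else z(H, H),
    W_xC = m(E, H), W_hC = m(H, H),
    W_xo = m(E, H), W_ho = m(H, H), W_co = if (peephole) m(H, H) else z(H, H),
    b_i = numeric(H), b_f = numeric(H), b_C = numeric(H), b_o = numeric(H)
  )
  attr(p, "peephole") <- peephole
  p
}

#' One step of the peephole LSTM cell
#'
#' Evaluates the five cell equations once (row-vector convention:
#' `x_t %*% W_xi` etc.).
#'
#' @param x_t input vector (length = input size).
#' @param h_prev,C_prev previous hidden and cell state vectors.
#' @param params [lstm_params()].
#' @return list with `h`, `C` (and the gate activations `i`, `f`, `g`,
#'   `o` for inspection).
#' @examples
#' p <- lstm_params(2, 3)
#' for (nm in names(p)) p[[nm]][] <- 0
#' lstm_step(c(1, 1), numeric(3), numeric(3), p)$i  # sigma(0) = 0.5
#' @export
lstm_step <- function(x_t, h_prev, C_prev, params) {
  p <- params
  i <- sigmoid(c(x_t %*% p$W_xi + h_prev %*% p$W_hi + C_prev %*% p$W_ci) + p$b_i)
  f <- sigmoid(c(x_t %*% p$W_xf + h_prev %*% p$W_hf + C_prev %*% p$W_cf) + p$b_f)
  g <- tanh(c(x_t %*% p$W_xC + h_prev %*% p$W_hC) + p$b_C)
  C <- f * C_prev + i * g
  o <- sigmoid(c(x_t %*% p$W_xo + h_prev %*% p$W_ho + C %*% p$W_co) + p$b_o)
  h <- o * tanh(C)
  list(h = h, C = C, i = i, f = f, g = g, o = o)
}

# --- whole-sequence forward/backward (training kernels) -----------------

# X: T x E. Returns hidden states H (T x Hd) and caches for backprop.
lstm_forward_seq <- function(X, p) {
  Tn <- nrow(X); Hd <- ncol(p$W_hi)
  Wh <- cbind(p$W_hi, p$W_hf, p$W_hC, p$W_ho)
  Wc <- cbind(p$W_ci, p$W_cf)
  XW <- X %*% cbind(p$W_xi, p$W_xf, p$W_xC, p$W_xo)
  b <- c(p$b_i, p$b_f, p$b_C, p$b_o)
  ii <- seq_len(Hd); fi <- Hd + ii; gi <- 2L * Hd + ii; oi <- 3L * Hd + ii
  I <- F_ <- G <- O <- C <- H <- matrix(0, Tn, Hd)
  h <- numeric(Hd); Cv <- numeric(Hd)
  for (t in seq_len(Tn)) {
    a <- XW[t, ] + c(h %*% Wh) + b
    pc <- c(Cv %*% Wc)
    i <- sigmoid(a[ii] + pc[ii])
    f <- sigmoid(a[fi] + pc[Hd + ii])
    g <- tanh(a[gi])
    Cv <- f * Cv + i * g
    o <- sigmoid(a[oi] + c(Cv %*% p$W_co))
    h <- o * tanh(Cv)
    I[t, ] <- i; F_[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- Cv; H[t, ] <- h
  }
  list(H = H, I = I, F = F_, G = G, O = O, C = C, X = X)
}

# dH: T x Hd gradient on the hidden outputs. Returns dX and parameter grads.
lstm_backward_seq <- function(cache, dH, p) {
  Tn <- nrow(dH); Hd <- ncol(dH)
  I <- cache$I; F_ <- cache$F; G <- cache$G; O <- cache$O; C <- cache$C
  Cprev <- rbind(rep(0, Hd), C[-Tn, , drop = FALSE])
  if (Tn == 1L) Cprev <- matrix(0, 1L, Hd)
  Hprev <- rbind(rep(0, Hd), cache$H[-Tn, , drop = FALSE])
  if (Tn == 1L) Hprev <- matrix(0, 1L, Hd)
  tC <- tanh(C)
  Wh_T <- t(cbind(p$W_hi, p$W_hf, p$W_hC, p$W_ho))
  DA <- matrix(0, Tn, 4L * Hd)
  ii <- seq_len(Hd); fi <- Hd + ii; gi <- 2L * Hd + ii; oi <- 3L * Hd + ii
  tWci <- t(p$W_ci); tWcf <- t(p$W_cf); tWco <- t(p$W_co)
  dh_rec <- numeric(Hd); dC_rec <- numeric(Hd)
  for (t in Tn:1L) {
    dh <- dH[t, ] + dh_rec
    do_ <- dh * tC[t, ]
    da_o <- do_ * O[t, ] * (1 - O[t, ])
    dC <- dC_rec + dh * O[t, ] * (1 - tC[t, ]^2) + c(da_o %*% tWco)
    di <- dC * G[t, ]
    df <- dC * Cprev[t, ]
    dg <- dC * I[t, ]
    da_i <- di * I[t, ] * (1 - I[t, ])
    da_f <- df * F_[t, ] * (1 - F_[t, ])
    da_g <- dg * (1 - G[t, ]^2)
    da <- c(da_i, da_f, da_g, da_o)
    DA[t, ] <- da
    dh_rec <- c(da %*% Wh_T)
    dC_rec <- dC * F_[t, ] + c(da_i %*% tWci) + c(da_f %*% tWcf)
  }
  dWx <- crossprod(cache$X, DA)
  dWh <- crossprod(Hprev, DA)
  db <- colSums(DA)
  grads <- list(
    W_xi = dWx[, ii], W_hi = dWh[, ii], W_ci = crossprod(Cprev, DA[, ii, drop = FALSE]),
    W_xf = dWx[, fi], W_hf = dWh[, fi], W_cf = crossprod(Cprev, DA[, fi, drop = FALSE]),
    W_xC = dWx[, gi], W_hC = dWh[, gi],
    W_xo = dWx[, oi], W_ho = dWh[, oi], W_co = crossprod(C, DA[, oi, drop = FALSE]),
    b_i = db[ii], b_f = db[fi], b_C = db[gi], b_o = db[oi]
  )
  dX <- DA %*% t(cbind(p$W_xi, p$W_xf, p$W_xC, p$W_xo))
  list(dX = dX, grads = grads)
}

# --- CRF output layer (shared DP kernels with the linear-chain CRF) -----

#' Negative log-likelihood of the CRF output layer
#'
#' `loss = log Z - (sum_t emission[t, y_t] + sum_t transition[y_{t-1},
#' y_t])`. Since `log Z` log-sum-exps over all paths including the gold
#' one, the loss is always >= 0.
#'
#' @param emissions T x L matrix of emission scores.
#' @param labels integer label ids (or character labels with `scheme`).
#' @param trans L x L transition matrix.
#' @param scheme optional [label_scheme()] for character labels.
#' @return list with `loss`, `d_emissions`, `d_trans` (gradients).
#' @export
crf_layer_nll <- function(emissions, labels, trans, scheme = NULL) {
  if (is.character(labels)) labels <- label_ids(labels, scheme)
  Tn <- nrow(emissions)
  if (length(labels) != Tn) stop_fmt("emissions/labels length mismatch")
  if (!all(is.finite(emissions))) stop_fmt("non-finite emissions")
  fb <- crf_batch_fb(emissions, lens = Tn, starts = 1L, trans)
  gold <- crf_gold_score(emissions, labels, lens = Tn, starts = 1L, trans)
  G <- fb$Gamma
  G[cbind(seq_len(Tn), labels)] <- G[cbind(seq_len(Tn), labels)] - 1
  d_trans <- fb$XI - crf_pair_counts(labels, lens = Tn, starts = 1L,
                                     L = ncol(emissions))
  list(loss = fb$logZ - gold, d_emissions = G, d_trans = d_trans)
}

#' Masked Viterbi decode of emission scores
#'
#' @param emissions T x L matrix.
#' @param trans L x L transition matrix.
#' @param scheme a [label_scheme()].
#' @param masked apply the BIO [transition_mask()] (default `TRUE`).
#' @return character vector of BIO labels (always well-formed when masked).
#' @export
crf_layer_decode <- function(emissions, trans, scheme = label_scheme(),
                             masked = TRUE) {
  if (!nrow(emissions)) stop_fmt("cannot decode an empty sequence")
  mask <- if (masked) transition_mask(scheme) else NULL
  scheme$labels[viterbi_core(emissions, trans, mask)]
}

# --- model -------------------------------------------------------------

#' Neural training configuration
#'
#' Defaults follow the standard recipe for character-level BiLSTM-CRF
#' clinical NER: embedding size 100, hidden dimension 100, at most 30
#' epochs, batch size 16, learning rate 0.01, gradient-norm clip 5,
#' dropout 0.5, Adam.
#'
#' @param embedding_size,hidden_size layer dimensions.
#' @param epochs maximum training epochs.
#' @param batch_size sequences per parameter update.
#' @param lr Adam learning rate.
#' @param clip gradient-norm clipping threshold.
#' @param dropout dropout rate in `[0, 1)`, applied to embeddings and
#'   encoder outputs during training.
#' @param unk_replace probability of replacing a character with the
#'   unknown id during training, so the unknown embedding is trained in
#'   context and characters unseen at test time decode sensibly (the
#'   standard singleton/unk-dropout device of character-level NER).
#' @param span_unk_replace probability of masking an entire gold entity
#'   span to unknown ids during training. Out-of-vocabulary mentions are
#'   contiguous runs of unseen characters; span masking teaches the
#'   encoder to type such runs from the surrounding clause context
#'   instead of memorizing surfaces.
#' @param patience early-stop patience on validation strict F1 (epochs).
#' @param peephole use the peephole cell (default) or the standard cell.
#' @param rng_seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `neural_train_config` list.
#' @export
neural_train_config <- function(embedding_size = 100L, hidden_size = 100L,
                                epochs = 30L, batch_size = 16L, lr = 0.01,
                                clip = 5, dropout = 0.5, unk_replace = 0.02,
                                span_unk_replace = 0.15, patience = 10L,
                                peephole = TRUE, rng_seed = 1L) {
  stopifnot(embedding_size > 0, hidden_size > 0, epochs > 0, batch_size > 0,
            lr > 0, clip > 0, dropout >= 0, dropout < 1,
            unk_replace >= 0, unk_replace < 1,
            span_unk_replace >= 0, span_unk_replace < 1, patience > 0)
  structure(list(embedding_size = as.integer(embedding_size),
                 hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, clip = clip,
                 dropout = dropout, unk_replace = unk_replace,
                 span_unk_replace = span_unk_replace,
                 patience = as.integer(patience),
                 peephole = peephole, rng_seed = as.integer(rng_seed)),
            class = "neural_train_config")
}

bilstm_init <- function(vocab, config, scheme) {
  E <- config$embedding_size; H <- config$hidden_size
  L <- length(scheme$labels)
  r <- 1 / sqrt(E)
  list(embedding = matrix(stats::runif((length(vocab) + 1L) * E, -r, r),
                          length(vocab) + 1L, E),  # last row = <unk>
       fwd = lstm_params(E, H, config$peephole),
       bwd = lstm_params(E, H, config$peephole),
       proj = matrix(stats::runif(2L * H * L, -1 / sqrt(2 * H), 1 / sqrt(2 * H)),
                     2L * H, L),
       proj_b = numeric(L),
       trans = matrix(0, L, L))
}

char_ids_of <- function(text, vocab_env, unk_id) {
  ch <- chars_of(text)
  ids <- integer(length(ch))
  for (k in seq_along(ch)) {
    ids[k] <- if (exists(ch[k], envir = vocab_env, inherits = FALSE)) {
      get(ch[k], envir = vocab_env)
    } else {
      unk_id
    }
  }
  ids
}

#' Encode characters into bidirectional context vectors
#'
#' Embeds the characters (unknown characters map to the trained unknown
#' row, or per-character vectors come from the optional external
#' embedding-provider hook), runs the forward LSTM and the backward LSTM
#' over the reversed sequence, and concatenates the two hidden states per
#' position. Inference mode: no dropout, deterministic.
#'
#' @param text a string (or an integer vector of character ids).
#' @param model a fitted `bilstm_crf_model`.
#' @return T x (2 * hidden) matrix of context vectors.
#' @export
bilstm_encode <- function(text, model) {
  X <- bilstm_embed(text, model)
  if (!nrow(X)) stop_fmt("cannot encode an empty sequence")
  Hf <- lstm_forward_seq(X, model$fwd)$H
  Tn <- nrow(X)
  Hb <- lstm_forward_seq(X[Tn:1L, , drop = FALSE], model$bwd)$H
  cbind(Hf, Hb[Tn:1L, , drop = FALSE])
}

bilstm_embed <- function(text, model) {
  if (!is.null(model$embedder) && is.character(text)) {
    X <- model$embedder(text)
    stopifnot(is.matrix(X), nrow(X) == nchar(text))
    return(X)
  }
  ids <- if (is.character(text)) {
    char_ids_of(text, model$vocab_env, model$unk_id)
  } else {
    as.integer(text)
  }
  model$embedding[ids, , drop = FALSE]
}

bilstm_emissions <- function(text, model) {
  Henc <- bilstm_encode(text, model)
  sweep(Henc %*% model$proj, 2L, model$proj_b, "+")
}

# --- Adam --------------------------------------------------------------

# nested-list Adam over named numeric arrays
adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      p2 <- p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps)
      list(p = p2, m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grad_global_norm <- function(g) {
  sqrt(sum(unlist(rapply(g, function(x) sum(x^2), how = "unlist"))))
}

scale_grads <- function(g, s) rapply(g, function(x) x * s, how = "replace")

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) add_grads(a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# --- training ----------------------------------------------------------

#' Train a BiLSTM-CRF character tagger
#'
#' Mini-batch training: per-sequence forward/backward through the
#' embedding, both LSTM directions, the emission projection and the CRF
#' layer; gradients are averaged over each mini-batch, clipped to global
#' norm `clip`, and applied with Adam. Dropout (inverted, seeded) is
#' applied to the embeddings and to the encoder outputs. After every epoch
#' the model is scored on the validation split with strict matching and
#' the best-F1 parameters are retained; training stops early when the
#' validation F1 has not improved for `patience` epochs. The vocabulary is
#' built from the training corpus; unseen characters share a trained
#' unknown embedding.
#'
#' @param train_docs,val_docs lists of `annotated_document`s.
#' @param config a [neural_train_config()].
#' @param scheme a [label_scheme()].
#' @param verbose print per-epoch loss and validation F1.
#' @return a `bilstm_crf_model` with a `history` data frame (epoch, mean
#'   train loss, validation P/R/F1).
#' @export
bilstm_crf_fit <- function(train_docs, val_docs,
                           config = neural_train_config(),
                           scheme = label_scheme(), verbose = FALSE) {
  if (!length(train_docs)) stop_fmt("no training documents")
  if (!length(val_docs)) stop_fmt("no validation documents")
  vocab <- unique(unlist(lapply(train_docs, function(d) chars_of(d$text))))
  L <- length(scheme$labels)
  with_seed(config$rng_seed, {
    params <- bilstm_init(vocab, config, scheme)
    model <- bilstm_assemble(params, vocab, scheme, config)
    seqs <- lapply(train_docs, function(d) {
      spans <- lapply(seq_len(nrow(d$mentions)), function(i) {
        (d$mentions$start[i] + 1L):d$mentions$end[i]
      })
      list(ids = char_ids_of(d$text, model$vocab_env, model$unk_id),
           labels = label_ids(to_bio(d, scheme)$labels, scheme),
           spans = spans)
    })
    opt <- adam_init(params)
    mask <- transition_mask(scheme)
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    history <- list()
    stale <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(seqs))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- zero_like(params)
        bl <- 0
        for (s in batch) {
          r <- bilstm_seq_grad(seqs[[s]], params, config, dropout = TRUE)
          acc <- add_grads(acc, r$grads)
          bl <- bl + r$loss
        }
        acc <- scale_grads(acc, 1 / length(batch))
        gn <- grad_global_norm(acc)
        if (!is.finite(gn)) {
          stop_fmt("divergence: non-finite gradient at epoch %d", epoch)
        }
        if (gn > config$clip) acc <- scale_grads(acc, config$clip / gn)
        upd <- adam_update(params, acc, opt, config$lr)
        params <- upd$params; opt <- upd$state
        epoch_loss <- epoch_loss + bl
      }
      if (!is.finite(epoch_loss)) {
        stop_fmt("divergence: non-finite loss at epoch %d", epoch)
      }
      model <- bilstm_assemble(params, vocab, scheme, config)
      val_pred <- bilstm_decode(model, val_docs)
      rep <- ner_score(val_pred, val_docs, "strict", scheme)
      vf1 <- overall_f1(rep)
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epoch_loss / length(seqs),
        val_precision = rep$precision[rep$type == "overall"],
        val_recall = rep$recall[rep$type == "overall"], val_f1 = vf1)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val strict F1 %.2f",
                        epoch, epoch_loss / length(seqs), vf1))
      }
      if (vf1 > best$f1) {
        best <- list(f1 = vf1, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    model <- bilstm_assemble(best$params, vocab, scheme, config)
    model$history <- do.call(rbind, history)
    model$best_epoch <- best$epoch
    model
  })
}

bilstm_assemble <- function(params, vocab, scheme, config) {
  env <- new.env(parent = emptyenv(), size = length(vocab))
  for (k in seq_along(vocab)) assign(vocab[k], k, envir = env)
  structure(c(params,
              list(vocab = vocab, vocab_env = env,
                   unk_id = length(vocab) + 1L, scheme = scheme,
                   config = config)),
            class = "bilstm_crf_model")
}

#' @export
print.bilstm_crf_model <- function(x, ...) {
  cat(sprintf("<bilstm_crf_model> vocab %d, embedding %d, hidden %d%s\n",
              length(x$vocab), ncol(x$embedding), ncol(x$fwd$W_hi),
              if (isTRUE(attr(x$fwd, "peephole"))) ", peephole" else ""))
  invisible(x)
}

# loss + full gradient for one sequence
bilstm_seq_grad <- function(seq, params, config, dropout = FALSE) {
  Tn <- length(seq$ids)
  H <- config$hidden_size
  ids <- seq$ids
  if (dropout) {
    unk_id <- nrow(params$embedding)
    if (config$span_unk_replace > 0 && length(seq$spans)) {
      for (sp in seq$spans) {
        if (stats::runif(1) < config$span_unk_replace) ids[sp] <- unk_id
      }
    }
    if (config$unk_replace > 0) {
      ids[stats::runif(Tn) < config$unk_replace] <- unk_id
    }
  }
  X <- params$embedding[ids, , drop = FALSE]
  if (dropout && config$dropout > 0) {
    keep <- 1 - config$dropout
    mx <- matrix(stats::rbinom(length(X), 1L, keep) / keep, nrow(X), ncol(X))
    X <- X * mx
  }
  fwd_cache <- lstm_forward_seq(X, params$fwd)
  bwd_cache <- lstm_forward_seq(X[Tn:1L, , drop = FALSE], params$bwd)
  Henc <- cbind(fwd_cache$H, bwd_cache$H[Tn:1L, , drop = FALSE])
  if (dropout && config$dropout > 0) {
    keep <- 1 - config$dropout
    mh <- matrix(stats::rbinom(length(Henc), 1L, keep) / keep,
                 nrow(Henc), ncol(Henc))
    Henc <- Henc * mh
  }
  emis <- sweep(Henc %*% params$proj, 2L, params$proj_b, "+")
  nll <- crf_layer_nll(emis, seq$labels, params$trans)
  dE <- nll$d_emissions
  g_proj <- crossprod(Henc, dE)
  g_proj_b <- colSums(dE)
  dHenc <- dE %*% t(params$proj)
  if (dropout && config$dropout > 0) dHenc <- dHenc * mh
  dHf <- dHenc[, seq_len(H), drop = FALSE]
  dHb <- dHenc[Tn:1L, H + seq_len(H), drop = FALSE]
  bf <- lstm_backward_seq(fwd_cache, dHf, params$fwd)
  bb <- lstm_backward_seq(bwd_cache, dHb, params$bwd)
  dX <- bf$dX + bb$dX[Tn:1L, , drop = FALSE]
  if (dropout && config$dropout > 0) dX <- dX * mx
  g_emb <- matrix(0, nrow(params$embedding), ncol(params$embedding))
  agg <- rowsum(dX, ids)
  g_emb[as.integer(rownames(agg)), ] <- agg
  list(loss = nll$loss,
       grads = list(embedding = g_emb, fwd = bf$grads, bwd = bb$grads,
                    proj = g_proj, proj_b = g_proj_b, trans = nll$d_trans))
}

#' Decode documents with a trained BiLSTM-CRF
#'
#' Deterministic inference: dropout off, masked Viterbi over the CRF
#' layer, strict BIO-to-mention conversion (safe under the mask).
#'
#' @param model a `bilstm_crf_model`.
#' @param docs list of `annotated_document`s (gold mentions ignored).
#' @return list of `annotated_document`s with predicted mentions.
#' @export
bilstm_decode <- function(model, docs) {
  lapply(docs, function(d) {
    emis <- bilstm_emissions(d$text, model)
    labels <- crf_layer_decode(emis, model$trans, model$scheme)
    seq <- bio_sequence(chars_of(d$text), labels, d$doc_type)
    annotated_document(d$doc_id, d$doc_type, d$text,
                       from_bio(seq, "strict", model$scheme))
  })
}

#' BiLSTM-CRF checkpoint I/O (weights + vocabulary + label scheme + config)
#'
#' @param model a `bilstm_crf_model`.
#' @param path file path (JSON).
#' @return `read_bilstm_model()`: a `bilstm_crf_model`.
#' @export
write_bilstm_model <- function(model, path) {
  obj <- list(format = "emrner-bilstm-crf", version = 1L,
              vocab = model$vocab,
              entity_types = model$scheme$entity_types,
              config = unclass(model$config),
              embedding = model$embedding,
              fwd = lapply(model$fwd, identity),
              bwd = lapply(model$bwd, identity),
              proj = model$proj, proj_b = model$proj_b, trans = model$trans)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bilstm_model
#' @export
read_bilstm_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "emrner-bilstm-crf")) {
    stop_fmt("'%s' is not a BiLSTM-CRF checkpoint", path)
  }
  config <- do.call(neural_train_config, as.list(obj$config))
  scheme <- label_scheme(obj$entity_types)
  fix <- function(p) {
    p <- lapply(p, function(x) if (is.matrix(x)) x else as.numeric(x))
    attr(p, "peephole") <- config$peephole
    p
  }
  params <- list(embedding = obj$embedding, fwd = fix(obj$fwd),
                 bwd = fix(obj$bwd), proj = obj$proj,
                 proj_b = as.numeric(obj$proj_b), trans = obj$trans)
  bilstm_assemble(params, obj$vocab, scheme, config)
}

#' Write a training log as JSONL
#'
#' One JSON object per epoch: epoch, mean train loss, validation P/R/F1.
#'
#' @param model a fitted `bilstm_crf_model`.
#' @param path file path.
#' @export
write_training_log <- function(model, path) {
  h <- model$history
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(h))) {
    writeLines(jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
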