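#' Linear-chain conditional random field
#'
#' From-scratch CRF over character BIO labels:
#' `P(y|x) = exp(sum_t emis(t, y_t) + sum_t trans(y_{t-1}, y_t)) / Z(x)`,
#' where the emission score of label `y` at position `t` is the sum of the
#' state weights `mu_k` of the (feature string, y) indicators active there,
#' and the transition score is a label-pair weight table (the `lambda_j`
#' realized as x-independent feature functions of `(y_{t-1}, y_t)`, the
#' convention of unigram-template CRF toolkits). Inference uses the scaled
#' forward-backward recursions; decoding uses Viterbi under a hard BIO
#' transition mask; training maximizes the L2-penalized log-likelihood with
#' a deterministic batch L-BFGS optimizer.
#'
#' @name linear-chain-crf
NULL

#' Construct a CRF model object
#'
#' @param vocab character vector of feature strings (the feature index is
#'   their position in this vector).
#' @param W numeric matrix `length(vocab) x L` of state-feature weights.
#' @param trans numeric `L x L` matrix of transition weights (from, to).
#' @param scheme a [label_scheme()].
#' @param feature_cfg the [feature_config()] the model was trained with.
#' @return a `crf_model`.
#' @export
crf_model <- function(vocab, W, trans, scheme = label_scheme(),
                      feature_cfg = feature_config()) {
  L <- length(scheme$labels)
  stopifnot(nrow(W) == length(vocab), ncol(W) == L,
            nrow(trans) == L, ncol(trans) == L,
            all(is.finite(W)), all(is.finite(trans)),
            !anyDuplicated(vocab))
  structure(list(vocab = vocab, W = W, trans = trans, scheme = scheme,
                 feature_cfg = feature_cfg),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model> %d features x %d labels\n",
              length(x$vocab), length(x$scheme$labels)))
  invisible(x)
}

# --- feature indexing --------------------------------------------------

# Stack featurized sequences into one sparse indicator matrix.
# featurized: output of featurize_corpus(). Unknown features (not in vocab)
# are dropped, which is the correct treatment at decode time.
crf_index <- function(featurized, vocab = NULL) {
  lens <- vapply(featurized, function(s) length(s$feats), integer(1))
  if (any(lens == 0L)) stop_fmt("cannot index an empty sequence")
  starts <- cumsum(c(1L, lens[-length(lens)]))
  sumT <- sum(lens)
  feat_list <- lapply(featurized, function(s) unlist(s$feats, use.names = FALSE))
  nf <- lapply(featurized, function(s) lengths(s$feats))
  all_feats <- unlist(feat_list, use.names = FALSE)
  rows <- rep.int(seq_len(sumT), unlist(nf, use.names = FALSE))
  if (is.null(vocab)) vocab <- unique(all_feats)
  ids <- match(all_feats, vocab)
  keep <- !is.na(ids)
  X <- Matrix::sparseMatrix(i = rows[keep], j = ids[keep], x = 1,
                            dims = c(sumT, length(vocab)))
  labels <- NULL
  if (!is.null(featurized[[1L]]$labels)) {
    labels <- unlist(lapply(featurized, `[[`, "labels"), use.names = FALSE)
  }
  list(X = X, lens = lens, starts = starts, vocab = vocab, labels = labels,
       seqid = rep.int(seq_along(lens), lens))
}

# --- scaled forward-backward, batched across sequences ------------------

# emis: stacked raw emission scores (sumT x L); returns per-sequence log Z,
# per-position posterior marginals Gamma, and the summed pairwise marginals
# XI (L x L), all exact.
crf_batch_fb <- function(emis, lens, starts, trans, want_marginals = TRUE) {
  L <- ncol(emis)
  n <- length(lens)
  sumT <- nrow(emis)
  rowmax <- emis[, 1L]
  for (j in 2:L) rowmax <- pmax(rowmax, emis[, j])
  Esc <- exp(emis - rowmax)
  trshift <- max(trans)
  expTr <- exp(trans - trshift)

  ord <- order(lens, decreasing = TRUE)
  lens_o <- lens[ord]; starts_o <- starts[ord]
  Tmax <- lens_o[1L]
  kt <- findInterval(-(1:Tmax), -lens_o)  # seqs with length >= t (sorted desc)
  rows_t <- lapply(seq_len(Tmax),
                   function(t) starts_o[seq_len(kt[t])] + t - 1L)

  AH <- matrix(0, sumT, L)
  CS <- numeric(sumT)
  A <- Esc[rows_t[[1L]], , drop = FALSE]
  c1 <- rowSums(A)
  A <- A / c1
  AH[rows_t[[1L]], ] <- A; CS[rows_t[[1L]]] <- c1
  logZ_o <- log(c1)
  if (Tmax > 1L) {
    for (t in 2:Tmax) {
      k <- kt[t]
      A2 <- (A[seq_len(k), , drop = FALSE] %*% expTr) *
        Esc[rows_t[[t]], , drop = FALSE]
      cc <- rowSums(A2)
      A <- A2 / cc
      AH[rows_t[[t]], ] <- A; CS[rows_t[[t]]] <- cc
      logZ_o[seq_len(k)] <- logZ_o[seq_len(k)] + log(cc)
    }
  }
  seqid <- rep.int(seq_len(n), lens)
  shift_sum <- as.vector(rowsum(rowmax, seqid))
  logZ <- numeric(n)
  logZ[ord] <- logZ_o
  logZ <- logZ + shift_sum + (lens - 1L) * trshift
  if (!want_marginals) return(list(logZ = logZ))

  BH <- matrix(0, sumT, L)
  B <- matrix(0, n, L)
  XI <- matrix(0, L, L)
  kt_next <- 0L
  for (t in Tmax:1L) {
    k <- kt[t]
    if (k > kt_next) {  # sequences ending exactly at t
      new <- (kt_next + 1L):k
      B[new, ] <- 1 / CS[starts_o[new] + t - 1L]
    }
    BH[rows_t[[t]], ] <- B[seq_len(k), , drop = FALSE]
    if (t > 1L) {
      EB <- Esc[rows_t[[t]], , drop = FALSE] * B[seq_len(k), , drop = FALSE]
      prev_rows <- rows_t[[t - 1L]][seq_len(k)]
      XI <- XI + (crossprod(AH[prev_rows, , drop = FALSE], EB) * expTr)
      B[seq_len(k), ] <- tcrossprod(EB, expTr) / CS[prev_rows]
    }
    kt_next <- k
  }
  Gamma <- AH * BH * CS
  list(logZ = logZ, Gamma = Gamma, XI = XI)
}

# gold path score (raw scale) for stacked sequences
crf_gold_score <- function(emis, labels, lens, starts, trans) {
  sumT <- nrow(emis)
  s <- sum(emis[cbind(seq_len(sumT), labels)])
  last <- starts + lens - 1L
  not_last <- setdiff(seq_len(sumT), last)
  if (length(not_last)) {
    s <- s + sum(trans[cbind(labels[not_last], labels[not_last + 1L])])
  }
  s
}

crf_pair_counts <- function(labels, lens, starts, L) {
  sumT <- length(labels)
  last <- starts + lens - 1L
  not_last <- setdiff(seq_len(sumT), last)
  if (!length(not_last)) return(matrix(0, L, L))
  idx <- (labels[not_last] - 1L) * L + labels[not_last + 1L]
  matrix(tabulate(idx, nbins = L * L), L, L, byrow = TRUE)
}

# --- exported inference operations -------------------------------------

crf_emissions <- function(feats, model) {
  Tn <- length(feats)
  L <- ncol(model$W)
  emis <- matrix(0, Tn, L)
  for (t in seq_len(Tn)) {
    ids <- match(feats[[t]], model$vocab)
    ids <- ids[!is.na(ids)]
    if (length(ids)) emis[t, ] <- colSums(model$W[ids, , drop = FALSE])
  }
  emis
}

#' Log partition function of a feature sequence
#'
#' `log Z(x)`: the log-sum-exp over all `|Y|^T` label sequences of the
#' total score, computed by the forward recursion in `O(T |Y|^2)`.
#'
#' @param feats a `feature_sequence` (list of per-position feature-string
#'   vectors).
#' @param model a [crf_model()].
#' @return scalar `log Z(x)`.
#' @export
crf_log_partition <- function(feats, model) {
  if (!length(feats)) stop_fmt("empty sequence")
  emis <- crf_emissions(feats, model)
  alpha <- emis[1L, ]
  Tn <- nrow(emis)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      alpha <- apply(alpha + model$trans, 2L, logsumexp) + emis[t, ]
    }
  }
  logsumexp(alpha)
}

# backward-recursion log Z, used to check forward/backward agreement
crf_log_partition_backward <- function(feats, model) {
  if (!length(feats)) stop_fmt("empty sequence")
  emis <- crf_emissions(feats, model)
  Tn <- nrow(emis)
  beta <- rep(0, ncol(emis))
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      beta <- apply(t(model$trans) + emis[t + 1L, ] + beta, 2L, logsumexp)
    }
  }
  logsumexp(emis[1L, ] + beta)
}

#' Log-probability of a label sequence
#'
#' `log P(y | x) = score(x, y) - log Z(x)`.
#'
#' @inheritParams crf_log_partition
#' @param labels character BIO labels or integer label ids, same length as
#'   `feats`.
#' @return scalar log-probability.
#' @export
crf_sequence_logprob <- function(feats, labels, model) {
  if (is.character(labels)) labels <- label_ids(labels, model$scheme)
  if (length(labels) != length(feats)) {
    stop_fmt("labels length %d != sequence length %d",
             length(labels), length(feats))
  }
  emis <- crf_emissions(feats, model)
  s <- sum(emis[cbind(seq_along(labels), labels)])
  if (length(labels) > 1L) {
    s <- s + sum(model$trans[cbind(labels[-length(labels)], labels[-1L])])
  }
  s - crf_log_partition(feats, model)
}

#' Posterior marginals of a feature sequence
#'
#' Per-position label marginals and the summed pairwise transition
#' marginals, from forward-backward.
#'
#' @inheritParams crf_log_partition
#' @return list with `Gamma` (T x L, rows sum to 1), `XI` (L x L), `logZ`.
#' @export
crf_marginals <- function(feats, model) {
  emis <- crf_emissions(feats, model)
  fb <- crf_batch_fb(emis, lens = length(feats), starts = 1L, model$trans)
  list(Gamma = fb$Gamma, XI = fb$XI, logZ = fb$logZ)
}

# Viterbi over raw emissions; mask is a transition_mask() list or NULL.
viterbi_core <- function(emis, trans, mask = NULL) {
  Tn <- nrow(emis); L <- ncol(emis)
  tr <- trans
  if (!is.null(mask)) {
    tr[!mask$trans] <- -Inf
    emis[1L, !mask$start] <- -Inf
  }
  delta <- emis[1L, ]
  psi <- matrix(0L, Tn, L)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      M <- delta + tr  # M[from, to]
      best <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(best, seq_len(L))] + emis[t, ]
      psi[t, ] <- best
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)  # first max: ties broken by label order
  if (Tn > 1L) {
    for (t in Tn:2L) path[t - 1L] <- psi[t, path[t]]
  }
  path
}

#' Viterbi decoding of a feature sequence
#'
#' Returns the argmax label path. The hard BIO transition mask is applied
#' by default, so the decoded path never contains `I-t` after `O` or after
#' a different entity type; ties are broken by label-scheme order.
#'
#' @inheritParams crf_log_partition
#' @param masked apply the [transition_mask()] (default `TRUE`).
#' @return character vector of BIO labels.
#' @export
crf_viterbi <- function(feats, model, masked = TRUE) {
  if (!length(feats)) stop_fmt("cannot decode an empty sequence")
  emis <- crf_emissions(feats, model)
  mask <- if (masked) transition_mask(model$scheme) else NULL
  model$scheme$labels[viterbi_core(emis, model$trans, mask)]
}

# --- training ----------------------------------------------------------

#' Penalized negative log-likelihood and gradient of a CRF
#'
#' `loss = -sum log P(y|x) + l2 * ||w||^2 / 2`; the gradient is expected
#' feature counts (forward-backward marginals) minus empirical counts plus
#' `l2 * w`, for both the state weights and the transition table.
#'
#' @param featurized labelled batch from [featurize_corpus()].
#' @param model a [crf_model()].
#' @param l2 L2 penalty strength (>= 0).
#' @return list with `loss`, `grad_W`, `grad_trans`.
#' @export
crf_nll_grad <- function(featurized, model, l2 = 0) {
  stopifnot(l2 >= 0)
  idx <- crf_index(featurized, vocab = model$vocab)
  if (is.null(idx$labels)) stop_fmt("batch has no gold labels")
  emis <- as.matrix(idx$X %*% model$W)
  fb <- crf_batch_fb(emis, idx$lens, idx$starts, model$trans)
  gold <- crf_gold_score(emis, idx$labels, idx$lens, idx$starts, model$trans)
  loss <- sum(fb$logZ) - gold +
    l2 / 2 * (sum(model$W^2) + sum(model$trans^2))
  if (!all(is.finite(loss))) stop_fmt("non-finite CRF loss")
  G <- fb$Gamma
  G[cbind(seq_len(nrow(G)), idx$labels)] <-
    G[cbind(seq_len(nrow(G)), idx$labels)] - 1
  grad_W <- as.matrix(Matrix::crossprod(idx$X, G)) + l2 * model$W
  L <- ncol(model$W)
  grad_trans <- fb$XI -
    crf_pair_counts(idx$labels, idx$lens, idx$starts, L) + l2 * model$trans
  list(loss = loss, grad_W = grad_W, grad_trans = grad_trans)
}

#' CRF training configuration
#'
#' @param l2 L2 regularization strength (default 1).
#' @param maxit maximum L-BFGS iterations.
#' @param factr L-BFGS convergence tolerance (see [stats::optim()]).
#' @param constrain_train apply the BIO transition mask during training by
#'   pinning forbidden transitions at a large negative score (default
#'   `FALSE`: the mask is an output-layer property applied at decode only).
#' @return a `crf_train_config` list.
#' @export
crf_train_config <- function(l2 = 1.0, maxit = 120L, factr = 1e8,
                             constrain_train = FALSE) {
  stopifnot(l2 >= 0, maxit >= 1)
  structure(list(l2 = l2, maxit = as.integer(maxit), factr = factr,
                 constrain_train = constrain_train),
            class = "crf_train_config")
}

#' Fit a linear-chain CRF by penalized maximum likelihood
#'
#' Deterministic batch optimization with L-BFGS-B: no seed sensitivity,
#' identical runs give identical models. Only feature/label combinations
#' observed in training are instantiated; unseen features keep weight 0
#' (they are dropped at decode time).
#'
#' @param docs training list of `annotated_document`s.
#' @param feature_cfg a [feature_config()] (one row of the ablation grid).
#' @param train_cfg a [crf_train_config()].
#' @param scheme a [label_scheme()].
#' @param segmenter,radicals see [char_observations()].
#' @param verbose print optimizer progress.
#' @return a fitted `crf_model` (with `fit` diagnostics attached).
#' @export
crf_fit <- function(docs, feature_cfg = feature_config(),
                    train_cfg = crf_train_config(),
                    scheme = label_scheme(),
                    segmenter = default_segmenter(),
                    radicals = radical_table(),
                    verbose = FALSE) {
  if (!length(docs)) stop_fmt("no training documents")
  featurized <- featurize_corpus(docs, feature_cfg, scheme,
                                 segmenter, radicals, labelled = TRUE)
  idx <- crf_index(featurized)
  if (!length(idx$vocab)) stop_fmt("no features observed in training data")
  L <- length(scheme$labels)
  nf <- length(idx$vocab)
  l2 <- train_cfg$l2

  mask <- transition_mask(scheme)
  free_tr <- if (train_cfg$constrain_train) which(mask$trans) else seq_len(L * L)
  pinned <- -30  # effectively forbidden when constrained

  unpack <- function(par) {
    W <- matrix(par[seq_len(nf * L)], nf, L)
    trans <- matrix(pinned, L, L)
    trans[free_tr] <- par[-seq_len(nf * L)]
    list(W = W, trans = trans)
  }
  emis_of <- function(W) as.matrix(idx$X %*% W)

  cache <- new.env(parent = emptyenv())
  fg <- function(par) {
    p <- unpack(par)
    emis <- emis_of(p$W)
    fb <- crf_batch_fb(emis, idx$lens, idx$starts, p$trans)
    gold <- crf_gold_score(emis, idx$labels, idx$lens, idx$starts, p$trans)
    loss <- sum(fb$logZ) - gold + l2 / 2 * sum(par^2)
    G <- fb$Gamma
    G[cbind(seq_len(nrow(G)), idx$labels)] <-
      G[cbind(seq_len(nrow(G)), idx$labels)] - 1
    gW <- as.matrix(Matrix::crossprod(idx$X, G))
    gT <- fb$XI - crf_pair_counts(idx$labels, idx$lens, idx$starts, L)
    grad <- c(gW, gT[free_tr]) + l2 * par
    cache$par <- par; cache$grad <- grad
    if (verbose) message(sprintf("  crf nll %.4f", loss))
    loss
  }
  gr <- function(par) {
    if (!identical(par, cache$par)) fg(par)
    cache$grad
  }

  par0 <- numeric(nf * L + length(free_tr))
  opt <- stats::optim(par0, fg, gr, method = "L-BFGS-B",
                      control = list(maxit = train_cfg$maxit,
                                     factr = train_cfg$factr))
  p <- unpack(opt$par)
  model <- crf_model(idx$vocab, p$W, p$trans, scheme, feature_cfg)
  model$fit <- list(value = opt$value, convergence = opt$convergence,
                    counts = opt$counts, train_cfg = train_cfg)
  model
}

#' Decode a corpus with a fitted CRF
#'
#' Featurizes each document with the model's feature configuration, runs
#' masked Viterbi, and converts the label paths back to entity mentions
#' (strict BIO decoding is safe because the mask forbids ill-formed paths).
#'
#' @param model a fitted `crf_model`.
#' @param docs list of `annotated_document`s (gold mentions ignored).
#' @param segmenter,radicals see [char_observations()].
#' @return list of `annotated_document`s carrying predicted mentions.
#' @export
crf_decode <- function(model, docs, segmenter = default_segmenter(),
                       radicals = radical_table()) {
  featurized <- featurize_corpus(docs, model$feature_cfg, model$scheme,
                                 segmenter, radicals, labelled = FALSE)
  idx <- crf_index(featurized, vocab = model$vocab)
  emis <- as.matrix(idx$X %*% model$W)
  mask <- transition_mask(model$scheme)
  lapply(seq_along(docs), function(s) {
    rows <- idx$starts[s]:(idx$starts[s] + idx$lens[s] - 1L)
    path <- viterbi_core(emis[rows, , drop = FALSE], model$trans, mask)
    labels <- model$scheme$labels[path]
    seq <- bio_sequence(chars_of(docs[[s]]$text), labels, docs[[s]]$doc_type)
    annotated_document(docs[[s]]$doc_id, docs[[s]]$doc_type, docs[[s]]$text,
                       from_bio(seq, mode = "strict", model$scheme))
  })
}

#' The 16-run feature ablation grid
#'
#' All on/off combinations of the POS, radical, document-type and
#' character-index streams (the character stream is always on), named in
#' `+pos+radical+type+index` style with `"base"` for the all-off run.
#'
#' @param half_width window half-width passed to every config.
#' @return named list of 16 [feature_config()]s.
#' @export
feature_ablation_grid <- function(half_width = 2L) {
  grid <- expand.grid(pos = c(FALSE, TRUE), radical = c(FALSE, TRUE),
                      type = c(FALSE, TRUE), index = c(FALSE, TRUE))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    nm <- paste0(if (g$pos) "+pos" else "",
                 if (g$radical) "+radical" else "",
                 if (g$type) "+type" else "",
                 if (g$index) "+index" else "")
    if (nm == "") nm <- "base"
    out[[nm]] <- feature_config(use_pos = g$pos, use_radical = g$radical,
                                use_doctype = g$type, use_index = g$index,
                                half_width = half_width)
  }
  out
}

#' CRF model JSON serialization
#'
#' Versioned JSON weights file with the feature index; identical training
#' runs serialize identically.
#'
#' @param model a `crf_model`.
#' @param path file path.
#' @return `read_crf_model()`: a `crf_model`.
#' @export
write_crf_model <- function(model, path) {
  obj <- list(format = "emrner-crf", version = 1L,
              entity_types = model$scheme$entity_types,
              vocab = model$vocab,
              W = model$W, trans = model$trans,
              feature_cfg = unclass(model$feature_cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_crf_model
#' @export
read_crf_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "emrner-crf")) {
    stop_fmt("'%s' is not a CRF model file", path)
  }
  scheme <- label_scheme(obj$entity_types)
  fc <- do.call(feature_config, as.list(obj$feature_cfg))
  crf_model(obj$vocab, obj$W, obj$trans, scheme, fc)
}
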