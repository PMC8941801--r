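# Independent oracles and fixture builders shared across test files.
# The oracles enumerate or hand-compute quantities without touching the
# package's dynamic-programming code paths.

# brute-force log partition: enumerate all |Y|^T label paths
enum_log_partition <- function(emis, trans) {
  L <- ncol(emis); Tn <- nrow(emis)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(L)), Tn)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(emis[cbind(seq_len(Tn), y)])
    if (Tn > 1L) s <- s + sum(trans[cbind(y[-Tn], y[-1L])])
    s
  })
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# brute-force posterior marginals (per-position and summed pairwise)
enum_marginals <- function(emis, trans) {
  L <- ncol(emis); Tn <- nrow(emis)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(L)), Tn)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(emis[cbind(seq_len(Tn), y)])
    if (Tn > 1L) s <- s + sum(trans[cbind(y[-Tn], y[-1L])])
    s
  })
  p <- exp(scores - max(scores)); p <- p / sum(p)
  Gamma <- matrix(0, Tn, L)
  XI <- matrix(0, L, L)
  for (r in seq_len(nrow(paths))) {
    y <- paths[r, ]
    Gamma[cbind(seq_len(Tn), y)] <- Gamma[cbind(seq_len(Tn), y)] + p[r]
    if (Tn > 1L) {
      for (t in 2:Tn) XI[y[t - 1L], y[t]] <- XI[y[t - 1L], y[t]] + p[r]
    }
  }
  list(Gamma = Gamma, XI = XI)
}

# brute-force argmax path (optionally under a transition mask)
enum_viterbi <- function(emis, trans, mask = NULL) {
  L <- ncol(emis); Tn <- nrow(emis)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(L)), Tn)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(emis[cbind(seq_len(Tn), y)])
    if (Tn > 1L) s <- s + sum(trans[cbind(y[-Tn], y[-1L])])
    if (!is.null(mask)) {
      if (!mask$start[y[1L]]) s <- -Inf
      if (Tn > 1L && !all(mask$trans[cbind(y[-Tn], y[-1L])])) s <- -Inf
    }
    s
  })
  list(path = paths[which.max(scores), ], score = max(scores))
}

# random tiny CRF instance (feature strings + model) for oracle suites
random_crf_instance <- function(Tn, n_types = 2L, n_feats = 8L,
                                scale = 1) {
  scheme <- label_scheme(paste0("t", seq_len(n_types)))
  L <- length(scheme$labels)
  vocab <- paste0("f", seq_len(n_feats))
  W <- matrix(stats::rnorm(n_feats * L, sd = scale), n_feats, L)
  trans <- matrix(stats::rnorm(L * L, sd = scale), L, L)
  feats <- lapply(seq_len(Tn), function(t) {
    sample(vocab, sample.int(3L, 1L))
  })
  labels <- sample.int(L, Tn, replace = TRUE)
  list(model = crf_model(vocab, W, trans, scheme), feats = feats,
       labels = labels, scheme = scheme)
}

# independent scalar evaluation of the five peephole cell equations
scalar_lstm_oracle <- function(x, h0, C0, p) {
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(p$W_xi[1, 1] * x + p$W_hi[1, 1] * h0 + p$W_ci[1, 1] * C0 + p$b_i[1])
  f <- sig(p$W_xf[1, 1] * x + p$W_hf[1, 1] * h0 + p$W_cf[1, 1] * C0 + p$b_f[1])
  g <- tanh(p$W_xC[1, 1] * x + p$W_hC[1, 1] * h0 + p$b_C[1])
  C1 <- f * C0 + i * g
  o <- sig(p$W_xo[1, 1] * x + p$W_ho[1, 1] * h0 + p$W_co[1, 1] * C1 + p$b_o[1])
  list(h = o * tanh(C1), C = C1, i = i, f = f, o = o)
}

# random mention set over a virtual document of length n
random_mentions <- function(n_doc = 50L, n_mentions = 5L,
                           types = emr_entity_types) {
  starts <- sort(sample.int(n_doc - 3L, n_mentions))
  ends <- pmin(starts + sample.int(4L, n_mentions, replace = TRUE), n_doc)
  entity_mention(content = strrep("x", ends - starts), start = starts,
                 end = ends, type = sample(types, n_mentions, replace = TRUE))
}

# wrap mention frames into single-document corpora for ner_score()
as_pred_gold <- function(pred_m, gold_m, n_doc = 60L) {
  text <- strrep("x", n_doc)
  keep_valid <- function(m) {
    m$content <- substring(rep(text, nrow(m)), m$start + 1L, m$end)
    m
  }
  list(pred = list(structure(list(doc_id = "d1", doc_type = "case",
                                  text = text, mentions = keep_valid(pred_m)),
                             class = "annotated_document")),
       gold = list(structure(list(doc_id = "d1", doc_type = "case",
                                  text = text, mentions = keep_valid(gold_m)),
                             class = "annotated_document")))
}

small_corpus <- function(n_patients = 5L, oov = 0, seed = 42L, ...) {
  generate_corpus(gen_config(n_patients = n_patients, oov_fraction = oov,
                             rng_seed = seed, ...))
}
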