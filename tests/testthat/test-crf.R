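test_that("zero-weight partition is T log |Y| and T=1 has the closed form", {
  sc <- label_scheme()  # 15 labels
  vocab <- c("f1", "f2")
  zero <- crf_model(vocab, matrix(0, 2, 15), matrix(0, 15, 15), sc)
  feats <- lapply(1:6, function(t) "f1")
  expect_equal(crf_log_partition(feats, zero), 6 * log(15), tolerance = 1e-12)
  # T = 1, two labels with state scores a and b
  sc2 <- label_scheme("a")  # labels O, B-a, I-a
  a <- 0.7; b <- -1.2
  m1 <- crf_model("f", matrix(c(a, b, -50), 1, 3), matrix(0, 3, 3), sc2)
  expect_equal(crf_log_partition(list("f"), m1),
               log(exp(a) + exp(b) + exp(-50)), tolerance = 1e-12)
})

test_that("forward partition, marginals and logprob match exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    inst <- random_crf_instance(Tn = sample(1:6, 1),
                                n_types = sample(1:2, 1))
    emis <- emrner:::crf_emissions(inst$feats, inst$model)
    lz <- crf_log_partition(inst$feats, inst$model)
    expect_equal(lz, enum_log_partition(emis, inst$model$trans),
                 tolerance = 1e-8)
    # forward and backward recursions agree
    expect_equal(lz, emrner:::crf_log_partition_backward(inst$feats,
                                                         inst$model),
                 tolerance = 1e-8)
    mar <- crf_marginals(inst$feats, inst$model)
    oracle <- enum_marginals(emis, inst$model$trans)
    expect_equal(max(abs(mar$Gamma - oracle$Gamma)), 0, tolerance = 1e-8)
    expect_equal(max(abs(mar$XI - oracle$XI)), 0, tolerance = 1e-8)
    expect_equal(max(abs(rowSums(mar$Gamma) - 1)), 0, tolerance = 1e-10)
    # probabilities over all paths sum to one
    L <- length(inst$scheme$labels)
    Tn <- length(inst$feats)
    if (L^Tn <= 200) {
      paths <- as.matrix(do.call(expand.grid, rep(list(1:L), Tn)))
      tot <- sum(apply(paths, 1, function(y) {
        exp(crf_sequence_logprob(inst$feats, y, inst$model))
      }))
      expect_equal(tot, 1, tolerance = 1e-8)
    }
  }
})

test_that("Viterbi equals brute-force argmax on 200 random small models", {
  set.seed(202)
  for (rep in 1:200) {
    inst <- random_crf_instance(Tn = sample(2:6, 1), n_types = 2)
    emis <- emrner:::crf_emissions(inst$feats, inst$model)
    got <- match(crf_viterbi(inst$feats, inst$model, masked = FALSE),
                 inst$scheme$labels)
    oracle <- enum_viterbi(emis, inst$model$trans)
    got_score <- sum(emis[cbind(seq_along(got), got)]) +
      sum(inst$model$trans[cbind(got[-length(got)], got[-1])])
    expect_equal(got_score, oracle$score, tolerance = 1e-9)
  }
})

test_that("masked Viterbi equals masked enumeration and zero weights give a valid path", {
  set.seed(203)
  sc <- label_scheme()
  mask <- transition_mask(sc)
  vocab <- paste0("g", 1:5)
  for (rep in 1:25) {
    Tn <- sample(2:4, 1)
    m <- crf_model(vocab, matrix(rnorm(5 * 15), 5, 15),
                   matrix(rnorm(225, sd = 0.5), 15, 15), sc)
    feats <- lapply(1:Tn, function(t) sample(vocab, 2))
    emis <- emrner:::crf_emissions(feats, m)
    got <- match(crf_viterbi(feats, m), sc$labels)
    oracle <- enum_viterbi(emis, m$trans, mask)
    got_score <- sum(emis[cbind(1:Tn, got)]) +
      sum(m$trans[cbind(got[-Tn], got[-1])])
    expect_equal(got_score, oracle$score, tolerance = 1e-9)
  }
  # zero-weight masked decode: ties broken by label order -> all O
  zero <- crf_model("f", matrix(0, 1, 15), matrix(0, 15, 15), sc)
  path <- crf_viterbi(lapply(1:5, function(t) "f"), zero)
  expect_identical(path, rep("O", 5))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(303)
  sc <- label_scheme(c("a", "b"))
  vocab <- paste0("f", 1:9)
  batch <- lapply(1:3, function(s) {
    Tn <- sample(3:5, 1)
    list(feats = lapply(1:Tn, function(t) sample(vocab, 2)),
         labels = sample.int(5, Tn, replace = TRUE))
  })
  W <- matrix(rnorm(9 * 5, sd = 0.5), 9, 5)
  Tr <- matrix(rnorm(25, sd = 0.5), 5, 5)
  m <- crf_model(vocab, W, Tr, sc)
  g <- crf_nll_grad(batch, m, l2 = 0.7)
  eps <- 1e-6
  for (k in sample(length(W), 15)) {
    W1 <- W; W1[k] <- W1[k] + eps
    W2 <- W; W2[k] <- W2[k] - eps
    num <- (crf_nll_grad(batch, crf_model(vocab, W1, Tr, sc), 0.7)$loss -
            crf_nll_grad(batch, crf_model(vocab, W2, Tr, sc), 0.7)$loss) /
      (2 * eps)
    expect_equal(g$grad_W[k], num, tolerance = 1e-5)
  }
  for (k in sample(25, 10)) {
    T1 <- Tr; T1[k] <- T1[k] + eps
    T2 <- Tr; T2[k] <- T2[k] - eps
    num <- (crf_nll_grad(batch, crf_model(vocab, W, T1, sc), 0.7)$loss -
            crf_nll_grad(batch, crf_model(vocab, W, T2, sc), 0.7)$loss) /
      (2 * eps)
    expect_equal(g$grad_trans[k], num, tolerance = 1e-5)
  }
})

test_that("zero-weight loss is sum of T log |Y| and gradients vanish at an optimum", {
  sc <- label_scheme(c("a", "b"))
  vocab <- c("u", "v")
  zero <- crf_model(vocab, matrix(0, 2, 5), matrix(0, 5, 5), sc)
  batch <- list(list(feats = lapply(1:4, function(t) "u"),
                     labels = c(1L, 2L, 3L, 1L)))
  g <- crf_nll_grad(batch, zero, l2 = 0)
  expect_equal(g$loss, 4 * log(5), tolerance = 1e-10)
  # separable toy problem: feature identifies the label
  sep <- lapply(1:6, function(s) {
    labs <- sample.int(5, 4, replace = TRUE)
    list(feats = lapply(labs, function(l) paste0("lab", l)),
         labels = labs)
  })
  fitted <- withr::with_seed(1, {
    docs <- NULL
    # direct optimization through crf_nll_grad on this tiny instance
    vocab2 <- paste0("lab", 1:5)
    W <- matrix(0, 5, 5); Tr <- matrix(0, 5, 5)
    for (iter in 1:300) {
      m2 <- crf_model(vocab2, W, Tr, sc)
      g2 <- crf_nll_grad(sep, m2, l2 = 0)
      W <- W - 0.5 * g2$grad_W; Tr <- Tr - 0.5 * g2$grad_trans
    }
    crf_nll_grad(sep, crf_model(vocab2, W, Tr, sc), l2 = 0)
  })
  expect_lt(max(abs(fitted$grad_W)), 1e-2)
  expect_lt(max(abs(fitted$grad_trans)), 1e-2)
})

test_that("crf_fit overfits a separable synthetic corpus (train strict F1 >= 0.99)", {
  corp <- small_corpus(n_patients = 5L, oov = 0, seed = 3L)
  model <- crf_fit(corp$train, feature_config(),
                   crf_train_config(maxit = 80L))
  expect_identical(model$fit$convergence, 0L)
  pred <- crf_decode(model, corp$train)
  rep <- ner_score(pred, corp$train, "strict")
  expect_gte(rep$f1[rep$type == "overall"] / 100, 0.99)
  # decoded output is always BIO-well-formed: strict from_bio never errors
  for (d in pred) expect_no_error(validate_document(d))
})

test_that("the ablation grid has 16 unique feature combinations", {
  grid <- feature_ablation_grid()
  expect_length(grid, 16L)
  expect_identical(anyDuplicated(names(grid)), 0L)
  expect_true("base" %in% names(grid))
  expect_true("+pos+radical+type+index" %in% names(grid))
  key <- vapply(grid, function(g) {
    paste(g$use_pos, g$use_radical, g$use_doctype, g$use_index)
  }, character(1))
  expect_identical(anyDuplicated(key), 0L)
})

test_that("model serialization round-trips to identical decodes", {
  corp <- small_corpus(n_patients = 3L, oov = 0, seed = 12L)
  model <- crf_fit(corp$train, feature_config(use_pos = FALSE),
                   crf_train_config(maxit = 40L))
  path <- withr::local_tempfile(fileext = ".json")
  write_crf_model(model, path)
  back <- read_crf_model(path)
  expect_equal(back$W, model$W, tolerance = 1e-12)
  p1 <- crf_decode(model, corp$test)
  p2 <- crf_decode(back, corp$test)
  for (i in seq_along(p1)) {
    expect_identical(as.data.frame(p1[[i]]$mentions),
                     as.data.frame(p2[[i]]$mentions))
  }
})
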