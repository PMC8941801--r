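test_that("lstm_step with zero parameters gives half-open gates and zero state", {
  p <- lstm_params(2, 3)
  for (nm in names(p)) p[[nm]][] <- 0
  st <- lstm_step(c(1, 1), numeric(3), numeric(3), p)
  expect_equal(st$i, rep(0.5, 3))
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$C, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
  # non-zero carried cell: C_t = c/2, h_t = tanh(c/2)/2
  cc <- c(0.4, -1.1, 2.0)
  st2 <- lstm_step(c(1, 1), numeric(3), cc, p)
  expect_equal(st2$C, 0.5 * cc, tolerance = 1e-12)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cc), tolerance = 1e-12)
})

test_that("lstm_step matches an independent scalar evaluation of the five equations", {
  set.seed(11)
  for (rep in 1:25) {
    p <- lstm_params(1, 1)
    x <- rnorm(1); h0 <- rnorm(1); C0 <- rnorm(1)
    got <- lstm_step(x, h0, C0, p)
    want <- scalar_lstm_oracle(x, h0, C0, p)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$C, want$C, tolerance = 1e-10)
  }
  # the whole-sequence kernel agrees with repeated single steps
  set.seed(12)
  p <- lstm_params(3, 4)
  X <- matrix(rnorm(15), 5, 3)
  run <- emrner:::lstm_forward_seq(X, p)
  h <- numeric(4); C <- numeric(4)
  for (t in 1:5) {
    st <- lstm_step(X[t, ], h, C, p)
    h <- st$h; C <- st$C
    expect_equal(run$H[t, ], h, tolerance = 1e-12)
    expect_equal(run$C[t, ], C, tolerance = 1e-12)
  }
})

test_that("full-model gradients match central finite differences", {
  set.seed(21)
  sc <- label_scheme(c("a", "b"))
  cfg <- neural_train_config(embedding_size = 3, hidden_size = 4,
                             dropout = 0, unk_replace = 0, rng_seed = 9)
  params <- emrner:::bilstm_init(c("x", "y", "z"), cfg, sc)
  seq1 <- list(ids = c(1L, 3L, 2L, 2L, 1L), labels = c(2L, 3L, 1L, 4L, 5L))
  r <- emrner:::bilstm_seq_grad(seq1, params, cfg)
  expect_gte(r$loss, 0)
  eps <- 1e-6
  poke <- function(path, k, e) {
    if (length(path) == 1L) params[[path]][k] <- params[[path]][k] + e
    else params[[path[1L]]][[path[2L]]][k] <-
      params[[path[1L]]][[path[2L]]][k] + e
    params
  }
  loss_of <- function(pp) emrner:::bilstm_seq_grad(seq1, pp, cfg)$loss
  cases <- list(
    list(c("fwd", "W_ci"), r$grads$fwd$W_ci),
    list(c("fwd", "W_co"), r$grads$fwd$W_co),
    list(c("bwd", "W_cf"), r$grads$bwd$W_cf),
    list(c("fwd", "W_hC"), r$grads$fwd$W_hC),
    list(c("bwd", "W_xo"), r$grads$bwd$W_xo),
    list(c("fwd", "b_C"), r$grads$fwd$b_C),
    list("embedding", r$grads$embedding),
    list("proj", r$grads$proj),
    list("trans", r$grads$trans)
  )
  for (cs in cases) {
    for (k in sample(length(cs[[2L]]), 4L)) {
      num <- (loss_of(poke(cs[[1L]], k, eps)) -
              loss_of(poke(cs[[1L]], k, -eps))) / (2 * eps)
      expect_equal(cs[[2L]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("encoding is bidirectional: reversing input swaps and reverses the halves", {
  set.seed(31)
  sc <- label_scheme()
  cfg <- neural_train_config(embedding_size = 4, hidden_size = 3,
                             dropout = 0, rng_seed = 5)
  params <- emrner:::bilstm_init(c("高", "血", "压"), cfg, sc)
  # tie the two directions so the symmetry is exact
  params$bwd <- params$fwd
  model <- emrner:::bilstm_assemble(params, c("高", "血", "压"), sc, cfg)
  H1 <- bilstm_encode("高血压", model)
  H2 <- bilstm_encode("压血高", model)
  Hd <- 3L
  expect_equal(H1[, 1:Hd], H2[nrow(H2):1L, Hd + 1:Hd], tolerance = 1e-12)
  expect_equal(H1[, Hd + 1:Hd], H2[nrow(H2):1L, 1:Hd], tolerance = 1e-12)
  # length-1 input: both directions see the same single step
  h1 <- bilstm_encode("高", model)
  expect_equal(h1[1, 1:Hd], h1[1, Hd + 1:Hd], tolerance = 1e-12)
  # inference is deterministic (no dropout at eval)
  expect_identical(bilstm_encode("高血压", model),
                   bilstm_encode("高血压", model))
})

test_that("the CRF layer loss is non-negative and decode maximizes emissions at T=1", {
  set.seed(41)
  sc <- label_scheme()
  for (rep in 1:20) {
    Tn <- sample(1:6, 1)
    emis <- matrix(rnorm(Tn * 15, sd = 2), Tn, 15)
    trans <- matrix(rnorm(225, sd = 0.5), 15, 15)
    labels <- sample.int(15, Tn, replace = TRUE)
    nll <- crf_layer_nll(emis, labels, trans)
    expect_gte(nll$loss, 0)
    if (Tn <= 3) {  # enumeration over 15^T paths stays cheap
      got <- match(crf_layer_decode(emis, trans, sc), sc$labels)
      oracle <- enum_viterbi(emis, trans, transition_mask(sc))
      s_got <- sum(emis[cbind(seq_len(Tn), got)])
      if (Tn > 1) s_got <- s_got + sum(trans[cbind(got[-Tn], got[-1])])
      expect_equal(s_got, oracle$score, tolerance = 1e-9)
    }
  }
  emis1 <- matrix(rnorm(15), 1, 15)
  lab <- crf_layer_decode(emis1, matrix(rnorm(225), 15, 15), sc)
  valid <- transition_mask(sc)$start
  expect_identical(lab, sc$labels[which.max(ifelse(valid, emis1, -Inf))])
})

test_that("masked decodes are always BIO-well-formed", {
  set.seed(51)
  sc <- label_scheme()
  for (rep in 1:300) {
    Tn <- sample(2:8, 1)
    emis <- matrix(rnorm(Tn * 15, sd = 3), Tn, 15)
    trans <- matrix(rnorm(225, sd = 2), 15, 15)
    lab <- crf_layer_decode(emis, trans, sc)
    seq <- bio_sequence(rep("x", Tn), lab, "case")
    expect_no_error(from_bio(seq, "strict"))
  }
})

test_that("training overfits a 10-sentence corpus to strict F1 1 within 30 epochs", {
  corp <- small_corpus(n_patients = 5L, oov = 0, seed = 11L)
  train10 <- corp$train[1:10]
  cfg <- neural_train_config(epochs = 30L, batch_size = 2L, dropout = 0,
                             unk_replace = 0, rng_seed = 4L)
  model <- bilstm_crf_fit(train10, train10, cfg)
  pred <- bilstm_decode(model, train10)
  rep <- ner_score(pred, train10, "strict")
  expect_equal(rep$f1[rep$type == "overall"], 100)
  expect_true(all(diff(model$history$epoch) == 1))
})

test_that("a fixed seed reproduces the loss curve exactly", {
  corp <- small_corpus(n_patients = 5L, oov = 0, seed = 14L)
  cfg <- neural_train_config(epochs = 3L, batch_size = 4L, rng_seed = 8L)
  m1 <- bilstm_crf_fit(corp$train, corp$validation, cfg)
  m2 <- bilstm_crf_fit(corp$train, corp$validation, cfg)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$embedding, m2$embedding)
})

test_that("checkpoints round-trip to identical predictions", {
  corp <- small_corpus(n_patients = 5L, oov = 0, seed = 15L)
  cfg <- neural_train_config(epochs = 2L, batch_size = 4L, rng_seed = 2L)
  model <- bilstm_crf_fit(corp$train, corp$validation, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_bilstm_model(model, path)
  back <- read_bilstm_model(path)
  p1 <- bilstm_decode(model, corp$test)
  p2 <- bilstm_decode(back, corp$test)
  for (i in seq_along(p1)) {
    expect_identical(as.data.frame(p1[[i]]$mentions),
                     as.data.frame(p2[[i]]$mentions))
  }
  log_path <- withr::local_tempfile(fileext = ".jsonl")
  write_training_log(model, log_path)
  lines <- readLines(log_path)
  expect_length(lines, nrow(model$history))
  expect_true(all(vapply(lines, jsonlite::validate, logical(1))))
})

test_that("an external embedding provider can replace the embedding table", {
  sc <- label_scheme()
  cfg <- neural_train_config(embedding_size = 4, hidden_size = 3,
                             dropout = 0, rng_seed = 6)
  withr::with_seed(6, {
    params <- emrner:::bilstm_init(c("头", "痛"), cfg, sc)
  })
  model <- emrner:::bilstm_assemble(params, c("头", "痛"), sc, cfg)
  model$embedder <- function(text) matrix(1, nchar(text), 4)
  H <- bilstm_encode("头晕眼花", model)  # unknown chars fine: provider decides
  expect_identical(dim(H), c(4L, 6L))
})
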