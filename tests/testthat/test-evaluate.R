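test_that("strict equality requires all four fields to match", {
  a <- entity_mention("水肿", 75, 77, "symptom")
  expect_true(strict_equal(a, entity_mention("水肿", 75, 77, "symptom")))
  expect_false(strict_equal(a, entity_mention("水肿", 75, 77, "body")))
  expect_false(strict_equal(a, entity_mention("水肿", 74, 76, "symptom")))
  # same span and type, differing content string
  b <- entity_mention("浮肿", 75, 77, "symptom")
  expect_false(strict_equal(b, a))
})

test_that("relaxed equality is type match plus the literal overlap inequality", {
  s <- entity_mention("xxx", 2, 5, "disease")
  expect_true(relaxed_equal(s, entity_mention("yyy", 3, 6, "disease")))
  expect_false(relaxed_equal(s, entity_mention("yy", 5, 7, "body")))
  expect_false(relaxed_equal(entity_mention("xx", 0, 2, "disease"),
                             entity_mention("yy", 5, 7, "disease")))
  # adjacency edge case: max(starts) == min(ends) satisfies the printed <=
  expect_true(relaxed_equal(entity_mention("xx", 0, 2, "disease"),
                            entity_mention("yy", 2, 4, "disease")))
  # literal three-clause variant additionally requires content equality
  expect_false(relaxed_equal(s, entity_mention("yyy", 3, 6, "disease"),
                             literal_content = TRUE))
  expect_true(relaxed_equal(s, entity_mention("xxx", 3, 6, "disease"),
                            literal_content = TRUE))
})

test_that("f1_score is the harmonic mean with the degenerate zero convention", {
  expect_equal(f1_score(50, 50), 50)
  expect_equal(f1_score(80, 80), 80)   # f1(p, p) = p
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(100, 0), 0)
  expect_error(f1_score(-1, 10))
  # printed-table worked examples at 2 d.p.
  expect_equal(round(f1_score(96.34, 94.81), 2), 95.57)
  expect_equal(round(f1_score(92.18, 87.63), 2), 89.85)
})

test_that("score handles exact, empty and partial prediction sets", {
  g <- random_mentions(50, 4)
  both <- as_pred_gold(g, g)
  rep <- ner_score(both$pred, both$gold, "strict")
  ov <- rep[rep$type == "overall", ]
  expect_equal(c(ov$precision, ov$recall, ov$f1), c(100, 100, 100))
  # S empty, G nonempty: P := 0, R = 0
  none <- as_pred_gold(random_mentions(50, 4)[0, ], g)
  rep0 <- ner_score(none$pred, none$gold, "strict")
  expect_equal(rep0$precision[rep0$type == "overall"], 0)
  expect_equal(rep0$recall[rep0$type == "overall"], 0)
  # 3 gold, 2 predictions, 1 strict match -> P=50, R=33.33, F1=40
  gold3 <- entity_mention(c("aa", "bb", "cc"), c(0, 10, 20), c(2, 12, 22),
                          c("symptom", "disease", "body"))
  pred2 <- entity_mention(c("aa", "zz"), c(0, 30), c(2, 32),
                          c("symptom", "body"))
  pg <- as_pred_gold(pred2, gold3)
  r <- ner_score(pg$pred, pg$gold, "strict")
  ov <- r[r$type == "overall", ]
  expect_equal(ov$precision, 50)
  expect_equal(ov$recall, 100 / 3, tolerance = 1e-12)
  expect_equal(round(ov$f1, 2), 40)
})

test_that("matching is one-to-one and symmetric under prediction/gold swap", {
  set.seed(61)
  for (rep in 1:50) {
    pg <- as_pred_gold(random_mentions(60, sample(1:6, 1)),
                       random_mentions(60, sample(1:6, 1)))
    for (mode in c("strict", "relaxed")) {
      r <- ner_score(pg$pred, pg$gold, mode)
      ov <- r[r$type == "overall", ]
      expect_lte(ov$n_matched, min(ov$n_pred, ov$n_gold))
      swapped <- ner_score(pg$gold, pg$pred, mode)
      so <- swapped[swapped$type == "overall", ]
      expect_equal(ov$precision, so$recall)
      expect_equal(ov$recall, so$precision)
    }
  }
})

test_that("every strict match is a relaxed match: relaxed P/R/F1 dominate strict", {
  set.seed(62)
  for (rep in 1:200) {
    pg <- as_pred_gold(random_mentions(60, sample(1:8, 1)),
                       random_mentions(60, sample(1:8, 1)))
    st <- ner_score(pg$pred, pg$gold, "strict")
    rx <- ner_score(pg$pred, pg$gold, "relaxed")
    expect_true(all(rx$precision >= st$precision - 1e-9))
    expect_true(all(rx$recall >= st$recall - 1e-9))
    expect_true(all(rx$f1 >= st$f1 - 1e-9))
  }
})

test_that("inter-annotator agreement follows the A1-as-gold formulas", {
  corp <- small_corpus(3L, seed = 19L)
  a1 <- corp$train[1:4]
  expect_equal(iaa_f1(a1, a1)$f1, 1)
  # A2 keeps the first half of each document's annotations
  a2 <- lapply(a1, function(d) {
    keep <- seq_len(ceiling(nrow(d$mentions) / 2))
    annotated_document(d$doc_id, d$doc_type, d$text,
                       d$mentions[keep, , drop = FALSE])
  })
  n1 <- sum(vapply(a1, function(d) nrow(d$mentions), integer(1)))
  n2 <- sum(vapply(a2, function(d) nrow(d$mentions), integer(1)))
  r <- iaa_f1(a1, a2)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, n2 / n1)
  expect_equal(r$f1, f1_score(1, n2 / n1))
  # disjoint annotation sets agree at 0
  a3 <- lapply(a1, function(d) annotated_document(d$doc_id, d$doc_type,
                                                  d$text))
  expect_equal(iaa_f1(a1, a3)$f1, 0)
})

test_that("comparison report flags the best F1 and renders a 19-row grid", {
  corp <- small_corpus(3L, seed = 23L)
  gold <- corp$test
  perfect <- gold
  worse <- lapply(gold, function(d) {
    annotated_document(d$doc_id, d$doc_type, d$text,
                       d$mentions[0, , drop = FALSE])
  })
  cmp <- model_comparison(list(good = perfect, bad = worse), gold)
  expect_true(cmp$best_strict[cmp$model == "good"])
  expect_false(cmp$best_strict[cmp$model == "bad"])
  expect_equal(cmp$strict_F1[1L], 100)
  # Table-4-shaped grid: dictionary + 16 CRF variants + 2 neural rows
  names19 <- c("dictionary", paste0("CRF ", names(feature_ablation_grid())),
               "BiLSTM-CRF", "BERT-BiLSTM-CRF")
  many <- stats::setNames(rep(list(perfect), 19L), names19)
  cmp19 <- model_comparison(many, gold)
  lines <- format(cmp19)
  expect_length(lines, 19L + 2L)
  expect_true(all(nchar(lines[-(1:2)]) > 0))
  expect_true(any(grepl("dictionary", lines)))
  expect_true(any(grepl("BERT-BiLSTM-CRF", lines)))
  # CSV output is re-readable
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(cmp19, path)
  expect_identical(nrow(utils::read.csv(path)), 19L)
})

test_that("the match audit writes one valid JSON record per prediction", {
  corp <- small_corpus(3L, seed = 29L)
  gold <- corp$test[1:2]
  dict <- build_dictionary(corp$train)
  pred <- recognize_corpus(gold, dict)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_match_audit(pred, gold, "strict", path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_identical(length(lines),
                   sum(vapply(pred, function(d) nrow(d$mentions), integer(1))))
  expect_true(all(vapply(lines, jsonlite::validate, logical(1))))
})
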