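#' Strict and relaxed mention matching
#'
#' Two mentions are strictly equal when content, start, end and entity type
#' are all equal. Relaxed (lenient) equality keeps type equality and the
#' span-overlap inequality `max(s.start, g.start) <= min(s.end, g.end)`;
#' the content-equality clause of the lenient definition is dropped by
#' default, because literal string equality with unequal boundaries is
#' self-contradictory ("content" denotes the semantic concept). Set
#' `literal_content = TRUE` for the literal three-clause variant. Under
#' end-exclusive spans the printed `<=` admits touching spans (adjacency);
#' it is implemented literally.
#'
#' @param s,g mentions data frames (compared row-wise after recycling a
#'   single row).
#' @param literal_content also require `s$content == g$content` in relaxed
#'   mode.
#' @return logical vector.
#' @export
strict_equal <- function(s, g) {
  s$content == g$content & s$start == g$start & s$end == g$end &
    s$type == g$type
}

#' @rdname strict_equal
#' @export
relaxed_equal <- function(s, g, literal_content = FALSE) {
  ok <- s$type == g$type & pmax(s$start, g$start) <= pmin(s$end, g$end)
  if (literal_content) ok <- ok & s$content == g$content
  ok
}

#' Harmonic-mean F1 of precision and recall
#'
#' `F1 = 2PR / (P + R)`, with `F1 = 0` when `P + R = 0`. Works on any
#' common scale (proportions or percentages).
#'
#' @param P,R non-negative precision and recall.
#' @return F1 on the same scale.
#' @examples
#' f1_score(96.34, 94.81)  # 95.57 at 2 d.p.
#' @export
f1_score <- function(P, R) {
  stopifnot(all(P >= 0), all(R >= 0))
  ifelse(P + R > 0, 2 * P * R / (P + R), 0)
}

# one-to-one greedy matching inside one document, gold-span order;
# ties broken by earliest predicted start. Returns number of matches
# (overall and per type).
match_mentions <- function(pred, gold, mode, literal_content = FALSE) {
  used <- rep(FALSE, nrow(pred))
  matched_type <- character(0)
  if (nrow(gold) && nrow(pred)) {
    gold <- gold[order(gold$start, gold$end), , drop = FALSE]
    ord_pred <- order(pred$start, pred$end)
    for (j in seq_len(nrow(gold))) {
      g <- gold[j, ]
      for (i in ord_pred) {
        if (used[i]) next
        hit <- if (mode == "strict") {
          strict_equal(pred[i, ], g)
        } else {
          relaxed_equal(pred[i, ], g, literal_content)
        }
        if (hit) {
          used[i] <- TRUE
          matched_type <- c(matched_type, g$type)
          break
        }
      }
    }
  }
  matched_type
}

#' Score predicted mentions against gold (per type and overall P/R/F1)
#'
#' Mentions are grouped by document; matching is one-to-one (each gold
#' matches at most one prediction), greedy in gold-span order. Precision is
#' `|matched| / |S|`, recall `|matched| / |G|`; the degenerate conventions
#' are `P := 0` when `|S| = 0`, `R := 0` when `|G| = 0`, `F1 := 0` when
#' `P + R = 0`. Values are percentages, unrounded (rendering rounds to 2
#' decimals).
#'
#' @param pred,gold lists of `annotated_document`s over the same doc_ids
#'   (predictions carry model output as their mentions).
#' @param mode `"strict"` or `"relaxed"`.
#' @param scheme a [label_scheme()].
#' @param literal_content see [relaxed_equal()].
#' @return an `eval_report` data frame: one row per entity type plus
#'   `overall`, columns `n_pred`, `n_gold`, `n_matched`, `precision`,
#'   `recall`, `f1`.
#' @export
ner_score <- function(pred, gold, mode = c("strict", "relaxed"),
                      scheme = label_scheme(), literal_content = FALSE) {
  mode <- match.arg(mode)
  pid <- vapply(pred, `[[`, character(1), "doc_id")
  gid <- vapply(gold, `[[`, character(1), "doc_id")
  if (!setequal(pid, gid) || anyDuplicated(pid) || anyDuplicated(gid)) {
    stop_fmt("prediction and gold corpora must cover the same doc_ids")
  }
  types <- scheme$entity_types
  n_pred <- n_gold <- n_match <- stats::setNames(integer(length(types)), types)
  for (d in pred) {
    g <- gold[[match(d$doc_id, gid)]]
    pm <- d$mentions; gm <- g$mentions
    for (ty in types) {
      n_pred[ty] <- n_pred[ty] + sum(pm$type == ty)
      n_gold[ty] <- n_gold[ty] + sum(gm$type == ty)
    }
    mt <- match_mentions(pm, gm, mode, literal_content)
    for (ty in mt) n_match[ty] <- n_match[ty] + 1L
  }
  row_of <- function(np, ng, nm) {
    P <- if (np > 0) 100 * nm / np else 0
    R <- if (ng > 0) 100 * nm / ng else 0
    c(precision = P, recall = R, f1 = f1_score(P, R))
  }
  rows <- t(vapply(types, function(ty) {
    row_of(n_pred[ty], n_gold[ty], n_match[ty])
  }, c(precision = 0, recall = 0, f1 = 0)))
  overall <- row_of(sum(n_pred), sum(n_gold), sum(n_match))
  out <- data.frame(
    type = c(types, "overall"),
    n_pred = c(unname(n_pred), sum(n_pred)),
    n_gold = c(unname(n_gold), sum(n_gold)),
    n_matched = c(unname(n_match), sum(n_match)),
    precision = c(rows[, "precision"], overall["precision"]),
    recall = c(rows[, "recall"], overall["recall"]),
    f1 = c(rows[, "f1"], overall["f1"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("eval_report", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("NER evaluation (%s matching)\n", attr(x, "mode") %||% "?"))
  y <- as.data.frame(x)
  y$precision <- sprintf("%.2f", round(y$precision, 2))
  y$recall <- sprintf("%.2f", round(y$recall, 2))
  y$f1 <- sprintf("%.2f", round(y$f1, 2))
  print(y, row.names = FALSE)
  invisible(x)
}

overall_f1 <- function(report) report$f1[report$type == "overall"]

#' Inter-annotator agreement F1
#'
#' One annotator (A1) is taken as the standard answer: precision is the
#' number of strictly consistent annotations over the total annotations of
#' A2, recall the same count over the total of A1, and the agreement is
#' their harmonic mean.
#'
#' @param a1,a2 lists of `annotated_document`s over the same doc_ids.
#' @return list with `precision`, `recall`, `f1` (proportions in `[0, 1]`).
#' @export
iaa_f1 <- function(a1, a2) {
  id1 <- vapply(a1, `[[`, character(1), "doc_id")
  id2 <- vapply(a2, `[[`, character(1), "doc_id")
  if (!setequal(id1, id2)) stop_fmt("annotator corpora cover different documents")
  n1 <- sum(vapply(a1, function(d) nrow(d$mentions), integer(1)))
  n2 <- sum(vapply(a2, function(d) nrow(d$mentions), integer(1)))
  consistent <- 0L
  for (d in a2) {
    g <- a1[[match(d$doc_id, id1)]]
    consistent <- consistent + length(match_mentions(d$mentions, g$mentions,
                                                     mode = "strict"))
  }
  P <- if (n2 > 0) consistent / n2 else 0
  R <- if (n1 > 0) consistent / n1 else 0
  list(precision = P, recall = R, f1 = f1_score(P, R))
}

#' Model-comparison report (strict and relaxed overall P/R/F1 per model)
#'
#' One row per named model with overall precision, recall and F1 under both
#' criteria; the highest F1 of each criterion is flagged.
#'
#' @param predictions named list of prediction corpora (lists of
#'   `annotated_document`s).
#' @param gold the gold corpus.
#' @param scheme a [label_scheme()].
#' @return a `model_comparison` data frame with columns `model`,
#'   `strict_P`, `strict_R`, `strict_F1`, `relaxed_P`, `relaxed_R`,
#'   `relaxed_F1`, `best_strict`, `best_relaxed`.
#' @export
model_comparison <- function(predictions, gold, scheme = label_scheme()) {
  stopifnot(length(predictions) >= 1, !is.null(names(predictions)))
  rows <- lapply(names(predictions), function(nm) {
    st <- ner_score(predictions[[nm]], gold, "strict", scheme)
    rx <- ner_score(predictions[[nm]], gold, "relaxed", scheme)
    so <- st[st$type == "overall", ]
    ro <- rx[rx$type == "overall", ]
    data.frame(model = nm,
               strict_P = so$precision, strict_R = so$recall,
               strict_F1 = so$f1,
               relaxed_P = ro$precision, relaxed_R = ro$recall,
               relaxed_F1 = ro$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best_strict <- out$strict_F1 == max(out$strict_F1)
  out$best_relaxed <- out$relaxed_F1 == max(out$relaxed_F1)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Render a model comparison as an aligned text table
#'
#' @param x a [model_comparison()].
#' @param ... unused.
#' @return the rendered lines, invisibly.
#' @export
format.model_comparison <- function(x, ...) {
  num <- function(v, best) {
    sprintf("%6.2f%s", round(v, 2), ifelse(best, "*", " "))
  }
  header <- sprintf("%-28s %7s %7s %7s  %7s %7s %7s",
                    "Model", "P", "R", "F1", "P", "R", "F1")
  sub <- sprintf("%-28s %23s  %23s", "", "-- strict --", "-- relaxed --")
  body <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-28s %6.2f  %6.2f  %s  %6.2f  %6.2f  %s",
            x$model[i], round(x$strict_P[i], 2), round(x$strict_R[i], 2),
            num(x$strict_F1[i], x$best_strict[i]),
            round(x$relaxed_P[i], 2), round(x$relaxed_R[i], 2),
            num(x$relaxed_F1[i], x$best_relaxed[i]))
  }, character(1))
  c(sub, header, body)
}

#' @export
print.model_comparison <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' @param x a [model_comparison()] or [ner_score()] report.
#' @param path file path.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Per-document match audit as JSONL
#'
#' One JSON object per predicted mention: the prediction, the matched gold
#' mention (or null), and the criterion used.
#'
#' @param pred,gold corpora as in [ner_score()].
#' @param mode `"strict"` or `"relaxed"`.
#' @param path file path.
#' @export
write_match_audit <- function(pred, gold, mode = c("strict", "relaxed"),
                              path) {
  mode <- match.arg(mode)
  gid <- vapply(gold, `[[`, character(1), "doc_id")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in pred) {
    g <- gold[[match(d$doc_id, gid)]]
    pm <- d$mentions
    if (!nrow(pm)) next
    gm <- g$mentions
    used <- rep(FALSE, nrow(pm))
    hit_of <- rep(NA_integer_, nrow(pm))
    if (nrow(gm)) {
      gm <- gm[order(gm$start, gm$end), , drop = FALSE]
      for (j in seq_len(nrow(gm))) {
        for (i in order(pm$start, pm$end)) {
          if (used[i]) next
          ok <- if (mode == "strict") strict_equal(pm[i, ], gm[j, ])
                else relaxed_equal(pm[i, ], gm[j, ])
          if (ok) { used[i] <- TRUE; hit_of[i] <- j; break }
        }
      }
    }
    for (i in seq_len(nrow(pm))) {
      rec <- list(doc_id = d$doc_id, criterion = mode,
                  prediction = as.list(pm[i, ]),
                  matched_gold = if (is.na(hit_of[i])) NULL
                                 else as.list(gm[hit_of[i], ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                 con)
    }
  }
  invisible(path)
}
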