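#' Default entity-frequency weights per (entity type, doc type)
#'
#' Sampling weights used by the synthetic generator, obtained by normalizing
#' the per-note-type token counts of the seven entity types observed in a
#' 500-patient neurosurgical corpus: symptoms dominate current-history
#' notes, past-history notes are rich in diseases, surgeries and
#' medications, family-history entities are concentrated almost entirely in
#' family-history notes, and disease-course phrases occur in case texts.
#'
#' @return a 7 x 4 numeric matrix, rows = [emr_entity_types], columns =
#'   [emr_doc_types]; each column sums to the token mass of that note type.
#' @export
default_gen_weights <- function() {
  w <- matrix(
    #  current  past  case family
    c(  14006,   180, 3982,     0,   # symptom
          929,    39,  971,     0,   # body
         1609,  3733,  984,     3,   # disease
            1,     2,   45,   196,   # family
          123,   605,  268,     0,   # surgery
          673,  2171,  154,     0,   # medication
            0,     0,  467,     0),  # progress
    nrow = 7, byrow = TRUE,
    dimnames = list(emr_entity_types, emr_doc_types))
  w
}

#' Generator configuration
#'
#' @param n_patients number of patients; each patient contributes one note
#'   of each of the four note types.
#' @param weights 7 x 4 non-negative matrix of entity-sampling weights per
#'   (entity type, doc type); defaults to [default_gen_weights()].
#' @param oov_fraction proportion of test-document mentions drawn from the
#'   held-out lexicon pool (out-of-vocabulary emulation), in `[0, 1]`.
#' @param negation_rate probability that a symptom slot is rendered negated
#'   ("无" + symptom); the symptom is still annotated, matching the
#'   annotation rule that negative symptoms are extracted.
#' @param hardcase_rate probability of the hard constructions: a body-region
#'   mention immediately followed by a symptom mention (e.g. 双下肢 + 水肿,
#'   adjacent non-overlapping spans), and "？"-separated double diagnoses.
#' @param clauses named list of `c(min, max)` clause counts per doc type.
#' @param rng_seed integer seed; identical config + seed gives a
#'   byte-identical corpus.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_patients = 500,
                       weights = default_gen_weights(),
                       oov_fraction = 0.1,
                       negation_rate = 0.2,
                       hardcase_rate = 0.1,
                       clauses = list(current = c(6, 10), past = c(4, 7),
                                      case = c(6, 9), family = c(2, 4)),
                       rng_seed = 1L) {
  stopifnot(n_patients >= 1, all(weights >= 0),
            oov_fraction >= 0, oov_fraction <= 1,
            negation_rate >= 0, negation_rate <= 1,
            hardcase_rate >= 0, hardcase_rate <= 1)
  structure(list(n_patients = as.integer(n_patients), weights = weights,
                 oov_fraction = oov_fraction, negation_rate = negation_rate,
                 hardcase_rate = hardcase_rate, clauses = clauses,
                 rng_seed = as.integer(rng_seed)),
            class = "gen_config")
}

# clause surface material, keyed by doc type / entity type ---------------

.gen_openers <- list(
  current = c("患者于入院前无明显诱因", "患者入院前", "现病史："),
  past = c("既往史：", "既往情况："),
  case = c("病例特点：中年患者", "病例摘要："),
  family = c("家族史：", "家族情况：")
)

.gen_sym_prefix <- list(
  current = c("出现", "伴", "自觉", "仍有"),
  past = c("曾有", "伴"),
  case = c("查体见", "伴", "出现"),
  family = c("伴")
)

.gen_dis_wrap <- list(
  current = list(c("外院诊断为", ""), c("检查提示", ""), c("考虑", "可能")),
  past = list(c("既往有", "病史"), c("患", "多年"), c("确诊", "3年")),
  case = list(c("辅助检查提示", ""), c("诊断为", ""), c("考虑", "")),
  family = list(c("患者本人有", "病史"))
)

.gen_fam_prefix <- c("其父患", "其母患有", "其兄患", "其祖母患")
.gen_sur_prefix <- c("曾行", "于外院行", "3年前行")
.gen_med_wrap <- list(c("长期口服", ""), c("予", "治疗"), c("规律服用", ""))
.gen_body_suffix <- c("无异常", "未见明显异常", "无压痛")

#' Generate one synthetic annotated EMR document
#'
#' Assembles clause templates appropriate to the note type, drawing entity
#' terms from the lexicon with the configured per-type weights; gold
#' mentions carry the exact character offsets of the inserted terms. Uses
#' the current RNG state (see [generate_corpus()] for seeded use).
#'
#' @param doc_type one of [emr_doc_types].
#' @param lexicon a [default_lexicon()]-style lexicon.
#' @param config a [gen_config()].
#' @param doc_id document identifier.
#' @param pool `"train"` to draw only from train pools, `"mixed"` to draw
#'   from the held-out pool with probability `config$oov_fraction`.
#' @return an `annotated_document`.
#' @export
generate_document <- function(doc_type, lexicon, config,
                              doc_id = "doc", pool = c("train", "mixed")) {
  pool <- match.arg(pool)
  stopifnot(doc_type %in% emr_doc_types)
  w <- config$weights[, doc_type]
  if (all(w == 0)) stop_fmt("all entity weights are zero for doc_type '%s'", doc_type)

  draw_term <- function(type) {
    p <- lexicon[[type]]
    use_heldout <- pool == "mixed" && length(p$heldout) &&
      stats::runif(1) < config$oov_fraction
    src <- if (use_heldout) p$heldout else p$train
    if (!length(src)) stop_fmt("empty lexicon pool for type '%s'", type)
    src[sample.int(length(src), 1L)]
  }

  buf <- character(0)
  cur <- 0L
  men <- vector("list", 0L)
  emit <- function(s) {
    if (nzchar(s)) {
      buf[[length(buf) + 1L]] <<- s
      cur <<- cur + nchar(s)
    }
  }
  emit_term <- function(type) {
    term <- draw_term(type)
    men[[length(men) + 1L]] <<-
      list(content = term, start = cur, end = cur + nchar(term), type = type)
    emit(term)
    term
  }

  pick <- function(x) x[[sample.int(length(x), 1L)]]

  clause <- function(type) {
    if (type == "symptom") {
      if (stats::runif(1) < config$hardcase_rate) {
        # body region immediately followed by a symptom: two adjacent mentions
        emit(pick(.gen_sym_prefix[[doc_type]]))
        emit_term("body"); emit_term("symptom")
      } else if (stats::runif(1) < config$negation_rate) {
        emit(pick(c("无", "否认"))); emit_term("symptom")
      } else {
        emit(pick(.gen_sym_prefix[[doc_type]])); emit_term("symptom")
      }
    } else if (type == "disease") {
      if (doc_type %in% c("current", "case") &&
          stats::runif(1) < config$hardcase_rate) {
        # "？"-separated uncertain double diagnosis
        emit("考虑"); emit_term("disease"); emit("？")
        emit_term("disease"); emit("？")
      } else {
        wrap <- pick(.gen_dis_wrap[[doc_type]])
        emit(wrap[1L]); emit_term("disease"); emit(wrap[2L])
      }
    } else if (type == "body") {
      emit_term("body"); emit(pick(.gen_body_suffix))
    } else if (type == "family") {
      emit(pick(.gen_fam_prefix)); emit_term("family")
    } else if (type == "surgery") {
      emit(pick(.gen_sur_prefix)); emit_term("surgery")
    } else if (type == "medication") {
      wrap <- pick(.gen_med_wrap)
      emit(wrap[1L]); emit_term("medication"); emit(wrap[2L])
    } else if (type == "progress") {
      emit_term("progress")
    } else {
      stop_fmt("unknown entity type '%s'", type)
    }
  }

  rng_cl <- config$clauses[[doc_type]]
  n_clauses <- sample.int(rng_cl[2L] - rng_cl[1L] + 1L, 1L) + rng_cl[1L] - 1L
  types <- sample(names(w), n_clauses, replace = TRUE, prob = w / sum(w))

  emit(pick(.gen_openers[[doc_type]]))
  for (k in seq_len(n_clauses)) {
    clause(types[k])
    emit(if (k < n_clauses) "，" else "。")
  }

  m <- if (length(men)) {
    entity_mention(vapply(men, `[[`, character(1), "content"),
                   vapply(men, `[[`, integer(1), "start"),
                   vapply(men, `[[`, integer(1), "end"),
                   vapply(men, `[[`, character(1), "type"))
  } else {
    empty_mentions()
  }
  annotated_document(doc_id, doc_type, paste(buf, collapse = ""), m)
}

#' Generate a seeded synthetic corpus with train/validation/test splits
#'
#' Each patient contributes four documents (one per note type); patients are
#' split 3:1:1 into train/validation/test. Test-document mentions are drawn
#' from the held-out lexicon pool with probability `config$oov_fraction`
#' (out-of-vocabulary emulation); train and validation documents draw only
#' from the train pools.
#'
#' @param config a [gen_config()] (needs `n_patients >= 3` for a non-empty
#'   split).
#' @param lexicon a lexicon, validated with [validate_lexicon()].
#' @return list with elements `train`, `validation`, `test`, each a list of
#'   `annotated_document`s.
#' @export
generate_corpus <- function(config = gen_config(),
                            lexicon = default_lexicon()) {
  stopifnot(config$n_patients >= 3)
  validate_lexicon(lexicon)
  n <- config$n_patients
  n_train <- floor(n * 3 / 5)
  n_val <- floor(n / 5)
  n_test <- n - n_train - n_val
  split_of <- rep(c("train", "validation", "test"),
                  c(n_train, n_val, n_test))
  with_seed(config$rng_seed, {
    docs <- list(train = list(), validation = list(), test = list())
    for (i in seq_len(n)) {
      sp <- split_of[i]
      pool <- if (sp == "test") "mixed" else "train"
      for (dt in emr_doc_types) {
        d <- generate_document(dt, lexicon, config,
                               doc_id = sprintf("p%04d_%s", i, dt),
                               pool = pool)
        docs[[sp]][[length(docs[[sp]]) + 1L]] <- d
      }
    }
    docs
  })
}

#' Mention and token counts per (doc type, entity type)
#'
#' Tokens are characters of the mention surface (so a single 双下肢 mention
#' contributes 3 body tokens). Totals equal the sums of the parts.
#'
#' @param corpus a list of `annotated_document`s.
#' @return data frame with columns `doc_type`, `entity_type`, `mentions`,
#'   `tokens`, including every (doc type, entity type) cell.
#' @export
corpus_stats <- function(corpus) {
  grid <- expand.grid(doc_type = emr_doc_types,
                      entity_type = emr_entity_types,
                      stringsAsFactors = FALSE)
  grid$mentions <- 0L
  grid$tokens <- 0L
  for (d in corpus) {
    m <- d$mentions
    if (!nrow(m)) next
    for (ty in unique(m$type)) {
      i <- which(grid$doc_type == d$doc_type & grid$entity_type == ty)
      sel <- m$type == ty
      grid$mentions[i] <- grid$mentions[i] + sum(sel)
      grid$tokens[i] <- grid$tokens[i] + sum(nchar(m$content[sel]))
    }
  }
  grid[order(match(grid$entity_type, emr_entity_types),
             match(grid$doc_type, emr_doc_types)), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Render corpus stats as a wide table (entity type x doc type)
#'
#' @param stats output of [corpus_stats()].
#' @param value `"tokens"` or `"mentions"`.
#' @return matrix with entity-type rows, doc-type columns, plus an `All` row.
#' @export
corpus_stats_table <- function(stats, value = c("tokens", "mentions")) {
  value <- match.arg(value)
  tab <- matrix(0L, length(emr_entity_types), length(emr_doc_types),
                dimnames = list(emr_entity_types, emr_doc_types))
  for (i in seq_len(nrow(stats))) {
    tab[stats$entity_type[i], stats$doc_type[i]] <- stats[[value]][i]
  }
  rbind(tab, All = colSums(tab))
}
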