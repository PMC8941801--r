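#' Pipeline run configuration
#'
#' A single flat key-value file (YAML) drives all pipeline commands;
#' command flags override config keys. All randomness flows from one
#' global seed fanned out per stage.
#'
#' @param path optional YAML file of overrides.
#' @param ... named overrides applied after the file.
#' @return a `run_config` list with generation parameters, training
#'   parameters, the CRF feature-ablation list and the global seed.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    n_patients = 500L,
    oov_fraction = 0.1,
    negation_rate = 0.2,
    hardcase_rate = 0.1,
    crf_l2 = 1.0,
    crf_maxit = 120L,
    crf_features = "+pos+radical+type",
    bilstm_epochs = 30L,
    bilstm_batch_size = 16L,
    bilstm_lr = 0.01,
    bilstm_clip = 5,
    bilstm_dropout = 0.5,
    bilstm_hidden = 100L,
    bilstm_embedding = 100L
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

ablation_from_names <- function(names, half_width = 2L) {
  grid <- feature_ablation_grid(half_width)
  missing <- setdiff(names, names(grid))
  if (length(missing)) {
    stop_fmt("unknown CRF feature combination(s): %s (valid: %s)",
             paste(missing, collapse = ", "),
             paste(names(grid), collapse = ", "))
  }
  grid[names]
}

write_manifest <- function(path, cfg, stage) {
  manifest <- list(stage = stage, seed = cfg$seed,
                   config = unclass(cfg),
                   package = "emrner",
                   package_version = as.character(utils::packageVersion("emrner")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

corpus_paths <- function(dir) {
  list(train = file.path(dir, "train.json"),
       validation = file.path(dir, "validation.json"),
       test = file.path(dir, "test.json"))
}

#' Pipeline commands
#'
#' Thin orchestration over the package's modules; each command reads and
#' writes only the declared plain-text formats (annotation JSON, BIO TSV,
#' dictionary/lexicon TSV, model JSON, report CSV) and writes a manifest
#' recording config, seed and versions.
#'
#' * `cmd_generate()` writes a seeded synthetic corpus (JSON + BIO TSV +
#'   lexicon TSV) under `out_dir`.
#' * `cmd_convert()` converts annotation JSON to BIO TSV.
#' * `cmd_build_dict()` builds a dictionary TSV from an annotated corpus.
#' * `cmd_train_crf()` / `cmd_train_bilstm()` fit models and write them.
#' * `cmd_predict()` decodes a corpus with a saved model.
#' * `cmd_evaluate()` scores predictions against gold.
#' * `cmd_compare()` runs dictionary + configured CRF ablations +
#'   BiLSTM-CRF end-to-end and renders the comparison table.
#'
#' @param cfg a [run_config()].
#' @param out_dir,path,... file locations and command-specific arguments
#'   (see each function's signature).
#' @return documented per command; file-writing commands return their
#'   output path(s) invisibly.
#' @name cli-pipeline
NULL

#' @rdname cli-pipeline
#' @export
cmd_generate <- function(out_dir, cfg = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gcfg <- gen_config(n_patients = cfg$n_patients,
                     oov_fraction = cfg$oov_fraction,
                     negation_rate = cfg$negation_rate,
                     hardcase_rate = cfg$hardcase_rate,
                     rng_seed = cfg$seed)
  lex <- default_lexicon()
  corpus <- generate_corpus(gcfg, lex)
  paths <- corpus_paths(out_dir)
  for (sp in names(paths)) {
    write_corpus_json(corpus[[sp]], paths[[sp]])
    write_bio_tsv(lapply(corpus[[sp]], to_bio), sub("\\.json$", ".bio.tsv",
                                                    paths[[sp]]))
  }
  write_lexicon_tsv(lex, file.path(out_dir, "lexicon.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), cfg, "generate")
  message(sprintf("generate: %d/%d/%d documents -> %s",
                  length(corpus$train), length(corpus$validation),
                  length(corpus$test), out_dir))
  invisible(paths)
}

#' @rdname cli-pipeline
#' @param json_in,tsv_out conversion inputs/outputs.
#' @export
cmd_convert <- function(json_in, tsv_out) {
  docs <- read_corpus_json(json_in)
  write_bio_tsv(lapply(docs, to_bio), tsv_out)
  message(sprintf("convert: %d documents -> %s", length(docs), tsv_out))
  invisible(tsv_out)
}

#' @rdname cli-pipeline
#' @param corpus_json annotated corpus to build from.
#' @param dict_out dictionary TSV path.
#' @export
cmd_build_dict <- function(corpus_json, dict_out) {
  docs <- read_corpus_json(corpus_json)
  dict <- build_dictionary(docs)
  write_dictionary_tsv(dict, dict_out)
  message(sprintf("build-dict: %d terms (%s) -> %s", length(dict$terms),
                  paste(names(dict$type_counts), dict$type_counts,
                        sep = ":", collapse = " "), dict_out))
  invisible(dict_out)
}

#' @rdname cli-pipeline
#' @param train_json training corpus path.
#' @param model_out model file path.
#' @param features CRF feature-combination name (e.g.
#'   `"+pos+radical+type"`, `"base"`).
#' @export
cmd_train_crf <- function(train_json, model_out, cfg = run_config(),
                          features = cfg$crf_features) {
  docs <- read_corpus_json(train_json)
  fc <- ablation_from_names(features)[[1L]]
  model <- crf_fit(docs, fc,
                   crf_train_config(l2 = cfg$crf_l2, maxit = cfg$crf_maxit))
  write_crf_model(model, model_out)
  write_manifest(paste0(model_out, ".manifest.json"), cfg, "train-crf")
  message(sprintf("train-crf [%s]: nll %.2f -> %s", features,
                  model$fit$value, model_out))
  invisible(model_out)
}

#' @rdname cli-pipeline
#' @param val_json validation corpus path.
#' @export
cmd_train_bilstm <- function(train_json, val_json, model_out,
                             cfg = run_config()) {
  train <- read_corpus_json(train_json)
  val <- read_corpus_json(val_json)
  ncfg <- neural_train_config(
    embedding_size = cfg$bilstm_embedding, hidden_size = cfg$bilstm_hidden,
    epochs = cfg$bilstm_epochs, batch_size = cfg$bilstm_batch_size,
    lr = cfg$bilstm_lr, clip = cfg$bilstm_clip,
    dropout = cfg$bilstm_dropout, rng_seed = cfg$seed)
  model <- bilstm_crf_fit(train, val, ncfg)
  write_bilstm_model(model, model_out)
  write_training_log(model, paste0(model_out, ".log.jsonl"))
  write_manifest(paste0(model_out, ".manifest.json"), cfg, "train-bilstm")
  message(sprintf("train-bilstm: best epoch %d (val F1 %.2f) -> %s",
                  model$best_epoch, max(model$history$val_f1), model_out))
  invisible(model_out)
}

read_any_model <- function(path) {
  head <- jsonlite::fromJSON(path)[["format"]]
  switch(head,
         "emrner-crf" = read_crf_model(path),
         "emrner-bilstm-crf" = read_bilstm_model(path),
         stop_fmt("unrecognized model file '%s'", path))
}

#' @rdname cli-pipeline
#' @param model_path saved model (CRF or BiLSTM-CRF; dictionary TSVs go
#'   through [read_dictionary_tsv()]).
#' @param pred_out predictions JSON path.
#' @export
cmd_predict <- function(model_path, corpus_json, pred_out) {
  docs <- read_corpus_json(corpus_json)
  pred <- if (grepl("\\.tsv$", model_path)) {
    recognize_corpus(docs, read_dictionary_tsv(model_path))
  } else {
    model <- read_any_model(model_path)
    if (inherits(model, "crf_model")) crf_decode(model, docs)
    else bilstm_decode(model, docs)
  }
  write_corpus_json(pred, pred_out)
  message(sprintf("predict: %d documents -> %s", length(pred), pred_out))
  invisible(pred_out)
}

#' @rdname cli-pipeline
#' @param pred_json,gold_json prediction and gold corpora.
#' @param criteria `"strict"` or `"relaxed"`.
#' @param report_out optional CSV output path.
#' @export
cmd_evaluate <- function(pred_json, gold_json,
                         criteria = c("strict", "relaxed"),
                         report_out = NULL) {
  criteria <- match.arg(criteria)
  rep <- ner_score(read_corpus_json(pred_json), read_corpus_json(gold_json),
                   criteria)
  print(rep)
  if (!is.null(report_out)) write_report_csv(rep, report_out)
  invisible(rep)
}

#' @rdname cli-pipeline
#' @param crf_runs character vector of CRF feature-combination names to
#'   include (defaults to the single combination in `cfg`; use
#'   `names(feature_ablation_grid())` for the full 16-run grid).
#' @param include_bilstm train and score the BiLSTM-CRF row.
#' @export
cmd_compare <- function(out_dir, cfg = run_config(),
                        crf_runs = cfg$crf_features,
                        include_bilstm = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gcfg <- gen_config(n_patients = cfg$n_patients,
                     oov_fraction = cfg$oov_fraction,
                     negation_rate = cfg$negation_rate,
                     hardcase_rate = cfg$hardcase_rate,
                     rng_seed = cfg$seed)
  corpus <- generate_corpus(gcfg)
  message(sprintf("compare: corpus %d/%d/%d documents",
                  length(corpus$train), length(corpus$validation),
                  length(corpus$test)))
  preds <- list()

  dict <- build_dictionary(corpus$train)
  preds[["dictionary"]] <- recognize_corpus(corpus$test, dict)
  message("compare: dictionary done")

  for (nm in crf_runs) {
    fc <- ablation_from_names(nm)[[1L]]
    model <- crf_fit(corpus$train, fc,
                     crf_train_config(l2 = cfg$crf_l2,
                                      maxit = cfg$crf_maxit))
    preds[[paste0("CRF ", nm)]] <- crf_decode(model, corpus$test)
    message(sprintf("compare: CRF %s done", nm))
  }

  if (include_bilstm) {
    ncfg <- neural_train_config(
      embedding_size = cfg$bilstm_embedding, hidden_size = cfg$bilstm_hidden,
      epochs = cfg$bilstm_epochs, batch_size = cfg$bilstm_batch_size,
      lr = cfg$bilstm_lr, clip = cfg$bilstm_clip,
      dropout = cfg$bilstm_dropout, rng_seed = cfg$seed)
    model <- bilstm_crf_fit(corpus$train, corpus$validation, ncfg)
    preds[["BiLSTM-CRF"]] <- bilstm_decode(model, corpus$test)
    message("compare: BiLSTM-CRF done")
  }

  cmp <- model_comparison(preds, corpus$test)
  print(cmp)
  write_report_csv(cmp, file.path(out_dir, "comparison.csv"))
  writeLines(format(cmp), file.path(out_dir, "comparison.txt"))
  write_manifest(file.path(out_dir, "manifest.json"), cfg, "compare")
  invisible(cmp)
}
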