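#' Per-character observation streams for CRF features
#'
#' Four observation streams are attached to every character of a document:
#' the part of speech of the enclosing word, the character's radical (the
#' indexing graphical component of a Han character, e.g. 疒), the document
#' type, and the character index in the paragraph (counted from 0).
#'
#' @name feature-streams
NULL

.radical_cache <- new.env(parent = emptyenv())

#' Packaged character-to-radical table
#'
#' Loads the radical mapping shipped with the package (covering the
#' synthetic lexicon plus common Han characters). Characters without a
#' radical (Latin letters, digits, punctuation) map to `"N"`.
#'
#' @param path optional path to a two-column `char\tradical` TSV; defaults
#'   to the packaged table.
#' @return named character vector, character -> radical.
#' @export
radical_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.radical_cache$default)) return(.radical_cache$default)
    path <- system.file("extdata", "radicals.tsv", package = "emrner")
  }
  lines <- sub("\r$", "", readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab <- stats::setNames(vapply(parts, `[[`, character(1), 2L),
                         vapply(parts, `[[`, character(1), 1L))
  if (is.null(.radical_cache$default) &&
      identical(path, system.file("extdata", "radicals.tsv",
                                  package = "emrner"))) {
    .radical_cache$default <- tab
  }
  tab
}

#' Built-in fallback segmenter
#'
#' Treats every character as a one-character word with POS tag `"X"`, so
#' the pipeline runs with no external word-segmentation model. A custom
#' segmenter is any function `text -> data.frame(word, pos)` whose words
#' concatenate back to the text (an adapter for an external Chinese
#' segmenter can be plugged in here).
#'
#' @return a segmenter function.
#' @export
default_segmenter <- function() {
  function(text) {
    ch <- chars_of(text)
    data.frame(word = ch, pos = rep("X", length(ch)),
               stringsAsFactors = FALSE)
  }
}

#' Compute per-character observations for a document
#'
#' Each character inherits the POS of the word it belongs to; the radical
#' is looked up per character (`"N"` for characters without a radical;
#' unknown Han characters also map to `"N"` with a warning); the document
#' type is copied; the character index counts from 0.
#'
#' @param doc an `annotated_document` (or any list with `text`, `doc_type`).
#' @param segmenter a segmenter function, see [default_segmenter()]; its
#'   output must be a partition of the text.
#' @param radicals a radical table, see [radical_table()].
#' @return data frame with columns `char`, `pos`, `radical`, `doc_type`,
#'   `char_index`.
#' @export
char_observations <- function(doc, segmenter = default_segmenter(),
                              radicals = radical_table()) {
  ch <- chars_of(doc$text)
  seg <- segmenter(doc$text)
  if (paste(seg$word, collapse = "") != doc$text) {
    stop_fmt("[%s] segmenter output is not a partition of the text",
             doc$doc_id %||% "?")
  }
  pos <- rep(seg$pos, nchar(seg$word))
  rad <- unname(radicals[ch])
  unknown_han <- is.na(rad) & grepl("^[一-鿿]$", ch)
  if (any(unknown_han)) {
    warning(sprintf("no radical entry for Han character(s): %s; using \"N\"",
                    paste(unique(ch[unknown_han]), collapse = " ")),
            call. = FALSE)
  }
  rad[is.na(rad)] <- "N"
  data.frame(char = ch, pos = pos, radical = rad,
             doc_type = rep(doc$doc_type, length(ch)),
             char_index = seq_along(ch) - 1L,
             stringsAsFactors = FALSE)
}

#' Feature template configuration
#'
#' With the default half-width 2 (content window 5) and the POS, radical
#' and document-type streams enabled, each position yields 16 unigram
#' templates: 5 character, 5 POS and 5 radical offsets plus the offset-free
#' document type. The raw character index is bucketed (0, 1-4, 5-9, 10-19,
#' 20+) to keep the feature space bounded; it is an optional 17th template.
#'
#' @param use_pos,use_radical,use_doctype,use_index enable the POS,
#'   radical, document-type and character-index streams.
#' @param half_width window half-width (window size = 2 * half_width + 1).
#' @return a `feature_config` list.
#' @export
feature_config <- function(use_pos = TRUE, use_radical = TRUE,
                           use_doctype = TRUE, use_index = FALSE,
                           half_width = 2L) {
  stopifnot(half_width >= 0)
  structure(list(use_pos = use_pos, use_radical = use_radical,
                 use_doctype = use_doctype, use_index = use_index,
                 half_width = as.integer(half_width)),
            class = "feature_config")
}

index_bucket <- function(i) {
  cut(i, breaks = c(-Inf, 0, 4, 9, 19, Inf),
      labels = c("0", "1-4", "5-9", "10-19", "20+"))
}

# windowed values of one stream at one offset, with boundary sentinels
.shift_stream <- function(values, offset) {
  n <- length(values)
  idx <- seq_len(n) + offset
  out <- rep(if (offset < 0) "<BOS>" else "<EOS>", n)
  ok <- idx >= 1L & idx <= n
  out[ok] <- values[idx[ok]]
  out
}

#' Expand observations through windowed unigram templates
#'
#' For each position emits unigram features `"<stream>[<offset>]=<value>"`
#' for offsets `-half_width .. +half_width` of each enabled stream (the
#' character stream is always on), plus the offset-free document type
#' (`"T=<doc_type>"`) and the bucketed character index (`"IDX=<bucket>"`)
#' when enabled. Out-of-range offsets yield `<BOS>`/`<EOS>` sentinels.
#' Identical inputs give identical feature strings.
#'
#' @param obs observations from [char_observations()].
#' @param config a [feature_config()].
#' @return a `feature_sequence`: list of per-position character vectors of
#'   feature strings, one element per character of the document.
#' @export
expand_features <- function(obs, config = feature_config()) {
  n <- nrow(obs)
  if (n == 0L) return(structure(list(), class = "feature_sequence"))
  offsets <- seq.int(-config$half_width, config$half_width)
  cols <- list()
  streams <- list(C = obs$char)
  if (config$use_pos) streams$P <- obs$pos
  if (config$use_radical) streams$R <- obs$radical
  for (nm in names(streams)) {
    for (off in offsets) {
      cols[[length(cols) + 1L]] <-
        sprintf("%s[%d]=%s", nm, off, .shift_stream(streams[[nm]], off))
    }
  }
  if (config$use_doctype) {
    cols[[length(cols) + 1L]] <- sprintf("T=%s", obs$doc_type)
  }
  if (config$use_index) {
    cols[[length(cols) + 1L]] <-
      sprintf("IDX=%s", as.character(index_bucket(obs$char_index)))
  }
  mat <- do.call(cbind, cols)
  feats <- lapply(seq_len(n), function(i) mat[i, ])
  structure(feats, class = "feature_sequence")
}

#' Feature dump (one position per line, tab-separated, blank line between
#' documents)
#'
#' @param featseqs list of `feature_sequence`s.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_feature_dump <- function(featseqs, path) {
  blocks <- vapply(featseqs, function(fs) {
    paste(vapply(fs, paste, character(1), collapse = "\t"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = FALSE)
  invisible(path)
}

#' Featurize a corpus for CRF training or decoding
#'
#' @param docs list of `annotated_document`s.
#' @param config a [feature_config()].
#' @param scheme a [label_scheme()].
#' @param segmenter,radicals see [char_observations()].
#' @param labelled attach gold BIO label ids (for training).
#' @return list of per-document lists with `feats` (feature_sequence),
#'   `labels` (integer label ids, when `labelled`), `doc`.
#' @export
featurize_corpus <- function(docs, config = feature_config(),
                             scheme = label_scheme(),
                             segmenter = default_segmenter(),
                             radicals = radical_table(),
                             labelled = TRUE) {
  lapply(docs, function(d) {
    obs <- char_observations(d, segmenter, radicals)
    out <- list(feats = expand_features(obs, config), doc = d)
    if (labelled) {
      out$labels <- label_ids(to_bio(d, scheme)$labels, scheme)
    }
    out
  })
}
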