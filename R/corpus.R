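#' Entity mentions
#'
#' A mention is a typed text span with 0-based, end-exclusive character
#' offsets: `end - start` equals the number of characters of `content`, and
#' `content` equals the document substring at `[start, end)`. Mentions are
#' kept as a data frame with columns `content`, `start`, `end`, `type`.
#'
#' @param content entity surface string(s).
#' @param start,end integer character offsets (0-based, end-exclusive).
#' @param type entity type, one of [emr_entity_types].
#' @return a `mentions` data frame.
#' @export
entity_mention <- function(content, start, end, type) {
  df <- data.frame(content = as.character(content),
                   start = as.integer(start), end = as.integer(end),
                   type = as.character(type), stringsAsFactors = FALSE)
  class(df) <- c("mentions", "data.frame")
  df
}

#' @rdname entity_mention
#' @export
empty_mentions <- function() {
  entity_mention(character(0), integer(0), integer(0), character(0))
}

bind_mentions <- function(...) {
  parts <- Filter(function(m) !is.null(m) && nrow(m) > 0, list(...))
  if (!length(parts)) return(empty_mentions())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("mentions", "data.frame")
  rownames(out) <- NULL
  out
}

#' Annotated EMR document
#'
#' A clinical note with its gold entity mentions. Mentions are sorted by
#' start offset and validated against the text (offsets in range, content
#' equal to the substring, no overlaps, known entity types).
#'
#' @param doc_id document identifier.
#' @param doc_type one of [emr_doc_types].
#' @param text the note text (a single UTF-8 string).
#' @param mentions a mentions data frame, see [entity_mention()].
#' @param scheme a [label_scheme()] giving the admissible entity types.
#' @param validate validate invariants (default `TRUE`).
#' @return an object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, doc_type, text,
                               mentions = empty_mentions(),
                               scheme = label_scheme(), validate = TRUE) {
  if (nrow(mentions)) {
    mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
    rownames(mentions) <- NULL
    class(mentions) <- c("mentions", "data.frame")
  }
  doc <- structure(list(doc_id = as.character(doc_id),
                        doc_type = as.character(doc_type),
                        text = as.character(text),
                        mentions = mentions),
                   class = "annotated_document")
  if (validate) validate_document(doc, scheme)
  doc
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document> %s [%s], %d chars, %d mentions\n",
              x$doc_id, x$doc_type, nchar(x$text), nrow(x$mentions)))
  invisible(x)
}

#' Validate an annotated document
#'
#' Checks the mention invariants: known entity type, `0 <= start < end <=
#' nchar(text)`, `end - start == nchar(content)`, `content` equal to the
#' text substring, and pairwise non-overlap. Errors name the document and
#' the offending record.
#'
#' @inheritParams annotated_document
#' @param doc an `annotated_document`.
#' @return `doc`, invisibly.
#' @export
validate_document <- function(doc, scheme = label_scheme()) {
  if (!doc$doc_type %in% emr_doc_types) {
    stop_fmt("[%s] unknown doc_type '%s'", doc$doc_id, doc$doc_type)
  }
  m <- doc$mentions
  n <- nchar(doc$text)
  if (!nrow(m)) return(invisible(doc))
  for (i in seq_len(nrow(m))) {
    if (!m$type[i] %in% scheme$entity_types) {
      stop_fmt("[%s] mention %d: unknown entity_type '%s'",
               doc$doc_id, i, m$type[i])
    }
    if (m$start[i] < 0 || m$end[i] <= m$start[i] || m$end[i] > n) {
      stop_fmt("[%s] mention %d ('%s'): offsets [%d,%d) out of range for %d-char text",
               doc$doc_id, i, m$content[i], m$start[i], m$end[i], n)
    }
    if (m$end[i] - m$start[i] != nchar(m$content[i])) {
      stop_fmt("[%s] mention %d ('%s'): span length %d != content length %d",
               doc$doc_id, i, m$content[i], m$end[i] - m$start[i],
               nchar(m$content[i]))
    }
    sub <- substr(doc$text, m$start[i] + 1L, m$end[i])
    if (sub != m$content[i]) {
      stop_fmt("[%s] mention %d: content '%s' != text substring '%s' at [%d,%d)",
               doc$doc_id, i, m$content[i], sub, m$start[i], m$end[i])
    }
  }
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m$start[i] < m$end[i - 1]) {
        stop_fmt("[%s] overlapping mentions: '%s' [%d,%d) and '%s' [%d,%d)",
                 doc$doc_id, m$content[i - 1], m$start[i - 1], m$end[i - 1],
                 m$content[i], m$start[i], m$end[i])
      }
    }
  }
  invisible(doc)
}

#' Convert offset annotations to a character-level BIO sequence
#'
#' The first character of each mention is tagged `B-type`, the remaining
#' characters `I-type`, and all other characters `O`.
#'
#' @param doc an `annotated_document` (validated; overlapping mentions are
#'   rejected).
#' @param scheme a [label_scheme()].
#' @return an object of class `bio_sequence` with elements `chars`,
#'   `labels`, `doc_type`.
#' @examples
#' d <- annotated_document("d1", "case", "考虑垂体瘤",
#'        entity_mention("垂体瘤", 2, 5, "disease"))
#' to_bio(d)$labels
#' @export
to_bio <- function(doc, scheme = label_scheme()) {
  validate_document(doc, scheme)
  ch <- chars_of(doc$text)
  labels <- rep("O", length(ch))
  m <- doc$mentions
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      labels[m$start[i] + 1L] <- paste0("B-", m$type[i])
      if (m$end[i] - m$start[i] > 1L) {
        labels[(m$start[i] + 2L):m$end[i]] <- paste0("I-", m$type[i])
      }
    }
  }
  bio_sequence(ch, labels, doc$doc_type)
}

#' @rdname to_bio
#' @param chars character vector (one code point per element).
#' @param labels BIO tags, same length as `chars`.
#' @param doc_type one of [emr_doc_types].
#' @export
bio_sequence <- function(chars, labels, doc_type) {
  stopifnot(length(chars) == length(labels))
  structure(list(chars = as.character(chars), labels = as.character(labels),
                 doc_type = as.character(doc_type)),
            class = "bio_sequence")
}

#' Recover entity mentions from a BIO label sequence
#'
#' Maximal `B-t (I-t)*` runs become mentions; `from_bio(to_bio(d))`
#' reproduces `d$mentions` exactly. In `"strict"` mode an orphan `I-t` tag
#' (one not preceded by `B-t`/`I-t` of the same type) is an error naming the
#' first bad position; in `"repair"` mode it is treated as `B-t`, which is
#' the tolerant decoding needed for models without transition constraints.
#'
#' @param seq a `bio_sequence`.
#' @param mode `"strict"` (default, for gold data) or `"repair"` (for
#'   predictions).
#' @param scheme a [label_scheme()]; labels are validated against it.
#' @return a mentions data frame.
#' @export
from_bio <- function(seq, mode = c("strict", "repair"),
                     scheme = label_scheme()) {
  mode <- match.arg(mode)
  labels <- seq$labels
  label_ids(labels, scheme)  # validates label vocabulary
  n <- length(labels)
  content <- character(0); start <- integer(0); end <- integer(0)
  type <- character(0)
  cur_type <- NA_character_; cur_start <- NA_integer_
  flush <- function(upto) {
    if (!is.na(cur_type)) {
      content <<- c(content, paste(seq$chars[(cur_start + 1L):upto],
                                   collapse = ""))
      start <<- c(start, cur_start); end <<- c(end, upto)
      type <<- c(type, cur_type)
    }
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") {
      flush(i - 1L); cur_type <- NA_character_
    } else {
      kind <- substr(lab, 1, 1)
      t <- substring(lab, 3)
      if (kind == "B") {
        flush(i - 1L); cur_type <- t; cur_start <- i - 1L
      } else {  # I-t
        if (is.na(cur_type) || cur_type != t) {
          if (mode == "strict") {
            stop_fmt("ill-formed BIO sequence: orphan %s at position %d (0-based %d)",
                     lab, i, i - 1L)
          }
          flush(i - 1L); cur_type <- t; cur_start <- i - 1L
        }
        # else: continue current entity
      }
    }
  }
  flush(n)
  entity_mention(content, start, end, type)
}

# JSON corpus I/O -------------------------------------------------------

#' Read and write annotation JSON corpora
#'
#' The on-disk format is a UTF-8 JSON list of objects `{"doc_id", "doc_type",
#' "text", "entities": [{"content", "start", "end", "type"}]}` with 0-based,
#' end-exclusive offsets. Reading validates every record; errors report the
#' `doc_id` of the offending record.
#'
#' @param path file path.
#' @param scheme a [label_scheme()].
#' @return `read_corpus_json()`: a list of `annotated_document`s.
#' @export
read_corpus_json <- function(path, scheme = label_scheme()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    ents <- rec$entities %||% list()
    m <- if (length(ents)) {
      entity_mention(
        content = vapply(ents, function(e) e$content, character(1)),
        start = vapply(ents, function(e) as.integer(e$start), integer(1)),
        end = vapply(ents, function(e) as.integer(e$end), integer(1)),
        type = vapply(ents, function(e) e$type, character(1))
      )
    } else {
      empty_mentions()
    }
    annotated_document(rec$doc_id, rec$doc_type, rec$text, m, scheme)
  })
}

#' @rdname read_corpus_json
#' @param docs list of `annotated_document`s.
#' @export
write_corpus_json <- function(docs, path) {
  out <- lapply(docs, function(d) {
    ents <- if (nrow(d$mentions)) {
      lapply(seq_len(nrow(d$mentions)), function(i) {
        list(content = d$mentions$content[i],
             start = d$mentions$start[i],
             end = d$mentions$end[i],
             type = d$mentions$type[i])
      })
    } else {
      list()
    }
    list(doc_id = d$doc_id, doc_type = d$doc_type, text = d$text,
         entities = ents)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

# BIO TSV I/O -----------------------------------------------------------

#' Read and write CoNLL-style BIO TSV
#'
#' One `<char>\t<label>` line per character, a `# doc_type=<t>` header line
#' per document, and a blank line between documents; UTF-8. CRLF line
#' endings are accepted on read.
#'
#' @param seqs list of `bio_sequence`s (a single sequence is also accepted).
#' @param path file path.
#' @param scheme a [label_scheme()]; labels are validated on read.
#' @return `read_bio_tsv()`: list of `bio_sequence`s.
#' @export
write_bio_tsv <- function(seqs, path) {
  if (inherits(seqs, "bio_sequence")) seqs <- list(seqs)
  blocks <- vapply(seqs, function(s) {
    paste0("# doc_type=", s$doc_type, "\n",
           paste(s$chars, s$labels, sep = "\t", collapse = "\n"))
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_bio_tsv
#' @export
read_bio_tsv <- function(path, scheme = label_scheme()) {
  lines <- sub("\r$", "", readLines(path, encoding = "UTF-8"))
  seqs <- list()
  chars <- character(0); labels <- character(0); doc_type <- NA_character_
  open <- FALSE
  flush <- function() {
    if (open) {
      label_ids(labels, scheme)
      seqs[[length(seqs) + 1L]] <<- bio_sequence(chars, labels, doc_type)
    }
    chars <<- character(0); labels <<- character(0)
    doc_type <<- NA_character_; open <<- FALSE
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, "# doc_type=")) {
      flush()
      doc_type <- substring(ln, nchar("# doc_type=") + 1L)
      open <- TRUE
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop_fmt("ragged BIO TSV line %d: '%s'", k, ln)
    }
    if (!open) { doc_type <- "current"; open <- TRUE }  # headerless block
    chars <- c(chars, parts[1L]); labels <- c(labels, parts[2L])
  }
  flush()
  seqs
}
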