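#' Build a domain entity dictionary from annotated documents
#'
#' Collects every annotated surface form with its entity type. A term
#' annotated with several types is stored under its most frequent type;
#' frequency ties are broken by the fixed entity-type order of the label
#' scheme, so builds are deterministic.
#'
#' @param docs list of `annotated_document`s (an empty list gives an empty
#'   dictionary).
#' @param scheme a [label_scheme()].
#' @return an `entity_dictionary`: list with `terms` (named character
#'   vector, term -> type), `max_term_length` (characters), and
#'   `type_counts` (unique terms per type).
#' @export
build_dictionary <- function(docs, scheme = label_scheme()) {
  term <- character(0); type <- character(0)
  for (d in docs) {
    if (nrow(d$mentions)) {
      term <- c(term, d$mentions$content)
      type <- c(type, d$mentions$type)
    }
  }
  terms <- character(0)
  if (length(term)) {
    tab <- table(term, type)
    order_pref <- match(colnames(tab), scheme$entity_types)
    resolved <- apply(tab, 1L, function(counts) {
      best <- which(counts == max(counts))
      colnames(tab)[best[order(order_pref[best])][1L]]
    })
    terms <- resolved
  }
  counts <- integer(length(scheme$entity_types))
  names(counts) <- scheme$entity_types
  if (length(terms)) {
    tc <- table(factor(terms, levels = scheme$entity_types))
    counts[names(tc)] <- as.integer(tc)
  }
  structure(list(terms = terms,
                 max_term_length = if (length(terms)) max(nchar(names(terms))) else 0L,
                 type_counts = counts),
            class = "entity_dictionary")
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf("<entity_dictionary> %d terms, max length %d\n",
              length(x$terms), x$max_term_length))
  print(x$type_counts)
  invisible(x)
}

#' Dictionary-based entity recognition by maximum string matching
#'
#' Greedy longest-match scan. In `"forward"` mode (default), at each
#' position the longest dictionary term starting there is emitted and the
#' scan advances past it; with no match the scan advances one character.
#' `"backward"` mode scans right-to-left preferring the longest term ending
#' at the current position. Output mentions are non-overlapping and sorted
#' by start.
#'
#' @param text a string.
#' @param dict an [build_dictionary()] result.
#' @param direction `"forward"` or `"backward"` maximum matching.
#' @return a mentions data frame.
#' @examples
#' docs <- list(annotated_document("d", "case", "考虑垂体瘤",
#'   entity_mention("垂体瘤", 2, 5, "disease")))
#' recognize(
#'   "考虑垂体瘤", build_dictionary(docs))
#' @export
recognize <- function(text, dict, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  ch <- chars_of(text)
  n <- length(ch)
  out <- list()
  if (!length(dict$terms) || n == 0L) return(empty_mentions())
  hash <- new.env(parent = emptyenv(), size = length(dict$terms))
  for (k in seq_along(dict$terms)) {
    assign(names(dict$terms)[k], dict$terms[[k]], envir = hash)
  }
  maxlen <- dict$max_term_length
  if (direction == "forward") {
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
        cand <- paste(ch[i:(i + len - 1L)], collapse = "")
        if (exists(cand, envir = hash, inherits = FALSE)) { hit <- len; break }
      }
      if (hit > 0L) {
        cand <- paste(ch[i:(i + hit - 1L)], collapse = "")
        out[[length(out) + 1L]] <- list(content = cand, start = i - 1L,
                                        end = i - 1L + hit,
                                        type = get(cand, envir = hash))
        i <- i + hit
      } else {
        i <- i + 1L
      }
    }
  } else {
    j <- n
    while (j >= 1L) {
      hit <- 0L
      for (len in seq.int(min(maxlen, j), 1L)) {
        cand <- paste(ch[(j - len + 1L):j], collapse = "")
        if (exists(cand, envir = hash, inherits = FALSE)) { hit <- len; break }
      }
      if (hit > 0L) {
        cand <- paste(ch[(j - hit + 1L):j], collapse = "")
        out[[length(out) + 1L]] <- list(content = cand, start = j - hit,
                                        end = j, type = get(cand, envir = hash))
        j <- j - hit
      } else {
        j <- j - 1L
      }
    }
    out <- rev(out)
  }
  if (!length(out)) return(empty_mentions())
  entity_mention(vapply(out, `[[`, character(1), "content"),
                 vapply(out, `[[`, integer(1), "start"),
                 vapply(out, `[[`, integer(1), "end"),
                 vapply(out, `[[`, character(1), "type"))
}

#' Apply dictionary recognition to a corpus
#'
#' @param docs list of `annotated_document`s (gold mentions are ignored).
#' @param dict an entity dictionary.
#' @param direction matching direction, see [recognize()].
#' @return list of `annotated_document`s carrying the predicted mentions.
#' @export
recognize_corpus <- function(docs, dict,
                             direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  lapply(docs, function(d) {
    annotated_document(d$doc_id, d$doc_type, d$text,
                       recognize(d$text, dict, direction))
  })
}

#' Dictionary TSV I/O (`<term>\t<type>`, UTF-8)
#'
#' The loader validates types against the label scheme.
#'
#' @param dict an entity dictionary.
#' @param path file path.
#' @param scheme a [label_scheme()].
#' @return `read_dictionary_tsv()`: an `entity_dictionary`.
#' @export
write_dictionary_tsv <- function(dict, path) {
  writeLines(paste(names(dict$terms), dict$terms, sep = "\t"), path,
             useBytes = FALSE)
  invisible(path)
}

#' @rdname write_dictionary_tsv
#' @export
read_dictionary_tsv <- function(path, scheme = label_scheme()) {
  lines <- sub("\r$", "", readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop_fmt("dictionary TSV line %d is not 2 columns", bad[1L])
  term <- vapply(parts, `[[`, character(1), 1L)
  type <- vapply(parts, `[[`, character(1), 2L)
  unknown <- setdiff(unique(type), scheme$entity_types)
  if (length(unknown)) {
    stop_fmt("dictionary TSV: unknown entity type(s): %s",
             paste(unknown, collapse = ", "))
  }
  terms <- stats::setNames(type, term)
  counts <- integer(length(scheme$entity_types))
  names(counts) <- scheme$entity_types
  tc <- table(factor(type, levels = scheme$entity_types))
  counts[names(tc)] <- as.integer(tc)
  structure(list(terms = terms,
                 max_term_length = if (length(terms)) max(nchar(term)) else 0L,
                 type_counts = counts),
            class = "entity_dictionary")
}
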