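#' Entity types and doc types of the clinical annotation scheme
#'
#' Seven entity types are recognized in neurosurgical EMR notes: symptoms,
#' body regions, diseases, family histories, surgeries, medications and
#' disease courses (`progress`). Each patient record contributes four note
#' types: current medical history, past medical history, case characteristics
#' and family history.
#'
#' @name scheme-constants
NULL

#' @rdname scheme-constants
#' @export
emr_entity_types <- c("symptom", "body", "disease", "family",
                      "surgery", "medication", "progress")

#' @rdname scheme-constants
#' @export
emr_doc_types <- c("current", "past", "case", "family")

#' BIO label scheme over a set of entity types
#'
#' Builds the character-level BIO tag set: the outside tag `O` first, then
#' `B-t` and `I-t` for each entity type in order. For the default seven
#' clinical entity types this yields 15 labels.
#'
#' @param entity_types ordered character vector of entity type names.
#' @return an object of class `label_scheme` with elements `entity_types`
#'   and `labels`.
#' @examples
#' sc <- label_scheme()
#' length(sc$labels)  # 15
#' @export
label_scheme <- function(entity_types = emr_entity_types) {
  stopifnot(is.character(entity_types), length(entity_types) >= 1,
            !anyDuplicated(entity_types))
  labels <- c("O", as.vector(rbind(paste0("B-", entity_types),
                                   paste0("I-", entity_types))))
  structure(list(entity_types = entity_types, labels = labels),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", length(x$entity_types), " entity types, ",
      length(x$labels), " labels\n", sep = "")
  cat("  ", paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

# label id helpers ------------------------------------------------------

label_ids <- function(labels, scheme) {
  ids <- match(labels, scheme$labels)
  if (anyNA(ids)) {
    bad <- unique(labels[is.na(ids)])
    stop_fmt("unknown label(s): %s", paste(bad, collapse = ", "))
  }
  ids
}

# Entity type / B-I structure of each label, used by transition masks and
# span decoding. Row 1 is "O".
label_parts <- function(scheme) {
  lab <- scheme$labels
  data.frame(
    label = lab,
    kind = ifelse(lab == "O", "O", substr(lab, 1, 1)),
    type = ifelse(lab == "O", NA_character_, substring(lab, 3)),
    stringsAsFactors = FALSE
  )
}

#' Allowed label-to-label transitions under the BIO grammar
#'
#' `I-t` may only follow `B-t` or `I-t` of the same type; every other
#' transition is allowed. The start-of-sequence row forbids `I-t` as the
#' first label. Used as a hard mask by Viterbi decoding so that decoded
#' sequences are always well-formed (in particular `I-X` never follows `O`).
#'
#' @param scheme a [label_scheme()].
#' @return list with `trans` (L x L logical, from x to) and `start`
#'   (length-L logical).
#' @export
transition_mask <- function(scheme) {
  parts <- label_parts(scheme)
  L <- nrow(parts)
  allowed <- matrix(TRUE, L, L, dimnames = list(parts$label, parts$label))
  for (j in seq_len(L)) {
    if (parts$kind[j] == "I") {
      ok_from <- parts$kind %in% c("B", "I") & parts$type == parts$type[j]
      ok_from[is.na(ok_from)] <- FALSE
      allowed[, j] <- ok_from
    }
  }
  start <- parts$kind != "I"
  names(start) <- parts$label
  list(trans = allowed, start = start)
}
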