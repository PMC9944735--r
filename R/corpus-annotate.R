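#' Construct an entity-type index
#'
#' Builds the lookup structure used to pair sentences with known
#' \verb{<entity, type>} pairs: a set of (surface, etype) rows plus a
#' case-folded lookup keyed by surface form. A surface form may map to more
#' than one type; lookups return all types ordered by `type_priority` (then
#' by first appearance), so downstream disambiguation is deterministic.
#'
#' @param surfaces Character vector of entity surface forms.
#' @param etypes Character vector of entity types, parallel to `surfaces`.
#' @param type_priority Optional character vector giving the precedence order
#'   of types when one surface form carries several.
#' @return An object of class `mnp_entity_index`.
#' @export
entity_index <- function(surfaces, etypes, type_priority = NULL) {
  stopifnot(length(surfaces) == length(etypes))
  keep <- nzchar(surfaces) & !is.na(surfaces) & !is.na(etypes)
  pairs <- unique(data.frame(surface = as.character(surfaces[keep]),
                             etype = as.character(etypes[keep]),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) stop("entity index must contain at least one pair")
  prio <- if (is.null(type_priority)) unique(pairs$etype) else
    c(type_priority, setdiff(unique(pairs$etype), type_priority))
  pairs <- pairs[order(match(pairs$etype, prio), seq_len(nrow(pairs))), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  lookup <- split(pairs$etype, tolower(pairs$surface))
  structure(list(pairs = pairs, lookup = lookup, type_priority = prio),
            class = "mnp_entity_index")
}

#' @export
print.mnp_entity_index <- function(x, ...) {
  cat(sprintf("<mnp_entity_index> %d pairs, %d surface forms, %d types\n",
              nrow(x$pairs), length(x$lookup), length(unique(x$pairs$etype))))
  invisible(x)
}

#' Types registered for a surface form
#'
#' @param index An [entity_index()].
#' @param surface A surface form (matched case-insensitively).
#' @return Character vector of types in priority order (empty if unknown).
#' @export
index_types <- function(index, surface) {
  stopifnot(inherits(index, "mnp_entity_index"))
  tps <- index$lookup[[tolower(surface)]]
  if (is.null(tps)) character(0) else unique(tps)
}

#' Create an annotated sentence
#'
#' @param text Normalized sentence text.
#' @param mentions data.frame with columns `surface`, `etype`, `start`, `end`
#'   (0-based inclusive code-point offsets into `text`).
#' @param tokens Optional precomputed token table; recomputed with
#'   [tokenize()] (forcing splits at mention boundaries) when omitted.
#' @return Object of class `mnp_sentence`.
#' @export
annotated_sentence <- function(text, mentions = empty_mentions(), tokens = NULL) {
  stopifnot(length(text) == 1L)
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  if (nrow(mentions)) {
    mentions$start <- as.integer(mentions$start)
    mentions$end <- as.integer(mentions$end)
    mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
    rownames(mentions) <- NULL
    nch <- nchar(text)
    bad <- mentions$start < 0L | mentions$end < mentions$start |
      mentions$end >= nch
    if (any(bad)) stop("mention span outside sentence bounds")
    if (any(nchar(mentions$surface) != mentions$end - mentions$start + 1L)) {
      stop("mention length inconsistent with its span")
    }
    intext <- substr(rep(text, nrow(mentions)), mentions$start + 1L,
                     mentions$end + 1L)
    if (any(tolower(intext) != tolower(mentions$surface))) {
      stop("mention surface does not match sentence text at its span")
    }
    if (nrow(mentions) > 1L &&
        any(mentions$start[-1L] <= mentions$end[-nrow(mentions)])) {
      stop("mentions overlap")
    }
  }
  if (is.null(tokens)) tokens <- tokenize(text, mention_spans = mentions)
  structure(list(text = text, tokens = tokens, mentions = mentions),
            class = "mnp_sentence")
}

#' @export
print.mnp_sentence <- function(x, ...) {
  cat(sprintf("<mnp_sentence> %d tokens, %d mentions: %s\n",
              nrow(x$tokens), nrow(x$mentions),
              substr(x$text, 1, 60)))
  invisible(x)
}

#' Empty mention table
#' @return Zero-row data.frame with the mention columns.
#' @export
empty_mentions <- function() {
  data.frame(surface = character(0), etype = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' Create an annotated document
#'
#' @param doc_id Document identifier.
#' @param sentences List of [annotated_sentence()] objects (at least one).
#' @return Object of class `mnp_document`.
#' @export
annotated_document <- function(doc_id, sentences) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.list(sentences), length(sentences) >= 1L)
  ok <- vapply(sentences, inherits, logical(1), what = "mnp_sentence")
  if (!all(ok)) stop("all elements of `sentences` must be mnp_sentence")
  structure(list(doc_id = doc_id, sentences = unname(sentences)),
            class = "mnp_document")
}

#' @export
print.mnp_document <- function(x, ...) {
  cat(sprintf("<mnp_document> '%s': %d sentences, %d mentions\n", x$doc_id,
              length(x$sentences),
              sum(vapply(x$sentences, function(s) nrow(s$mentions), integer(1)))))
  invisible(x)
}

#' Split a raw document into candidate sentences and filter them
#'
#' Normalizes the text, splits it into sentences, and keeps only sentences
#' whose token count lies in `[min_len, max_len]` and which contain at least
#' one surface form present in the entity index — the preprocessing rule that
#' discards sentences without valid entities or of unsuitable length.
#'
#' @param raw_doc Raw document text.
#' @param index An [entity_index()].
#' @param min_len,max_len Inclusive bounds on sentence length in tokens.
#' @return Character vector of retained (normalized) sentences; may be empty.
#' @export
split_and_filter <- function(raw_doc, index, min_len = 5L, max_len = 120L) {
  stopifnot(inherits(index, "mnp_entity_index"),
            min_len > 0L, min_len < max_len)
  sents <- split_sentences(normalize_text(raw_doc))
  if (length(sents) == 0L) return(character(0))
  surfaces <- unique(index$pairs$surface)
  keep <- vapply(sents, function(s) {
    ntok <- nrow(tokenize(s))
    if (ntok < min_len || ntok > max_len) return(FALSE)
    low <- tolower(s)
    for (sf in surfaces) {
      if (grepl(tolower(sf), low, fixed = TRUE)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  sents[keep]
}

#' Pair sentences with indexed entities
#'
#' Retrieves every indexed surface form occurring in each sentence and turns
#' the occurrences into typed mentions with offsets from [locate_span()].
#' Overlapping candidate matches are resolved longest-match-first, then
#' left-to-right. When a surface form is registered under several types, the
#' first type in the index's priority order is kept and the alternatives are
#' recorded in the returned report.
#'
#' @param sentences Character vector of normalized sentences.
#' @param index An [entity_index()].
#' @param doc_id Document id for the resulting document.
#' @return A list with `doc` (an [annotated_document()]; `NULL` when
#'   `sentences` is empty) and `ambiguous` (data.frame reporting surface
#'   forms whose alternative types were discarded).
#' @export
pair_entities <- function(sentences, index, doc_id = "doc") {
  stopifnot(inherits(index, "mnp_entity_index"))
  surfaces <- unique(index$pairs$surface)
  surfaces <- surfaces[order(-nchar(surfaces))] # longest first
  amb <- list()
  sents <- lapply(sentences, function(s) {
    taken <- rep(FALSE, nchar(s)) # character positions already claimed
    rows <- list()
    for (sf in surfaces) {
      hits <- find_occurrences(s, sf)
      if (nrow(hits) == 0L) next
      tps <- index_types(index, sf)
      for (h in seq_len(nrow(hits))) {
        st <- hits$start[h]; en <- hits$end[h]
        if (any(taken[(st + 1L):(en + 1L)])) next
        taken[(st + 1L):(en + 1L)] <- TRUE
        intext <- substr(s, st + 1L, en + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          surface = intext, etype = tps[1L], start = st, end = en,
          stringsAsFactors = FALSE)
        if (length(tps) > 1L) {
          amb[[length(amb) + 1L]] <<- data.frame(
            surface = sf, kept = tps[1L],
            alternatives = paste(tps[-1L], collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
    mentions <- if (length(rows)) do.call(rbind, rows) else empty_mentions()
    annotated_sentence(s, mentions)
  })
  ambiguous <- if (length(amb)) unique(do.call(rbind, amb)) else
    data.frame(surface = character(0), kept = character(0),
               alternatives = character(0), stringsAsFactors = FALSE)
  if (length(ambiguous$surface)) {
    warning(sprintf("%d surface form(s) map to multiple types; kept first by priority",
                    nrow(ambiguous)), call. = FALSE)
  }
  doc <- if (length(sents)) annotated_document(doc_id, sents) else NULL
  list(doc = doc, ambiguous = ambiguous)
}
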