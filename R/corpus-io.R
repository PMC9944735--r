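#' Write documents to a CoNLL-style token/tag file
#'
#' UTF-8, one `token<TAB>tag` pair per line, blank line after every sentence,
#' and a `-DOCSTART- <doc_id>` separator line (followed by a blank line)
#' before each document. Tags are produced with [spans_to_bio()].
#'
#' @param docs List of [annotated_document()] objects.
#' @param path Output file path.
#' @param scheme Tagging scheme passed to [spans_to_bio()].
#' @param docstart Document separator prefix (default `"-DOCSTART-"`).
#' @return `path`, invisibly.
#' @export
write_conll <- function(docs, path, scheme = "BIO", docstart = "-DOCSTART-") {
  lines <- character(0)
  for (d in docs) {
    lines <- c(lines, paste(docstart, d$doc_id), "")
    for (s in d$sentences) {
      tags <- spans_to_bio(s, scheme = scheme)
      lines <- c(lines, paste(s$tokens$token, tags, sep = "\t"), "")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read documents from a CoNLL-style token/tag file
#'
#' Inverse of [write_conll()]. Sentence text is reconstructed by joining
#' tokens with single spaces; mention spans are recovered from the BIO tags
#' with [bio_to_spans()], so `write_conll(read_conll(path))` reproduces a
#' well-formed file byte for byte. Malformed BIO openings (`I-` with no
#' matching `B-`) are repaired and counted in the `"repairs"` attribute.
#'
#' @param path Input file path.
#' @param docstart Document separator prefix.
#' @return List of [annotated_document()] objects, with attribute
#'   `"repairs"` giving the total number of BIO repairs applied.
#' @export
read_conll <- function(path, docstart = "-DOCSTART-") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  repairs <- 0L
  cur_id <- NULL
  cur_sents <- list()
  toks <- character(0); tags <- character(0)
  flush_sentence <- function() {
    if (length(toks) == 0L) return(invisible(NULL))
    text <- paste(toks, collapse = " ")
    ends <- cumsum(nchar(toks) + 1L) - 2L
    starts <- ends - nchar(toks) + 1L
    tok <- data.frame(token = toks, start = starts, end = ends,
                      stringsAsFactors = FALSE)
    stub <- structure(list(text = text, tokens = tok,
                           mentions = empty_mentions()),
                      class = "mnp_sentence")
    rec <- bio_to_spans(tags, stub)
    repairs <<- repairs + rec$repairs
    cur_sents[[length(cur_sents) + 1L]] <<-
      annotated_sentence(text, rec$mentions, tokens = tok)
    toks <<- character(0); tags <<- character(0)
    invisible(NULL)
  }
  flush_doc <- function() {
    flush_sentence()
    if (!is.null(cur_id) && length(cur_sents)) {
      docs[[length(docs) + 1L]] <<- annotated_document(cur_id, cur_sents)
    }
    cur_sents <<- list()
    invisible(NULL)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, docstart)) {
      flush_doc()
      cur_id <- trimws(substr(line, nchar(docstart) + 1L, nchar(line)))
      if (!nzchar(cur_id)) cur_id <- sprintf("doc%03d", length(docs) + 1L)
      next
    }
    if (!nzchar(trimws(line))) {
      flush_sentence()
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1L])) {
      stop(sprintf("malformed CoNLL line %d: '%s'", ln, line))
    }
    if (is.null(cur_id)) cur_id <- "doc001"
    toks <- c(toks, parts[1L])
    tags <- c(tags, parts[2L])
  }
  flush_doc()
  structure(docs, repairs = repairs)
}

# -- JSON-lines span format ---------------------------------------------------

doc_to_list <- function(d) {
  list(doc_id = d$doc_id,
       sentences = lapply(d$sentences, function(s) {
         list(text = s$text,
              mentions = if (nrow(s$mentions)) {
                lapply(seq_len(nrow(s$mentions)), function(i) {
                  list(surface = s$mentions$surface[i],
                       etype = s$mentions$etype[i],
                       start = s$mentions$start[i],
                       end = s$mentions$end[i])
                })
              } else list())
       }))
}

list_to_doc <- function(x) {
  sents <- lapply(x$sentences, function(s) {
    mentions <- if (length(s$mentions)) {
      do.call(rbind, lapply(s$mentions, function(m) {
        data.frame(surface = m$surface, etype = m$etype,
                   start = as.integer(m$start), end = as.integer(m$end),
                   stringsAsFactors = FALSE)
      }))
    } else empty_mentions()
    annotated_sentence(s$text, mentions)
  })
  annotated_document(x$doc_id, sents)
}

#' Write documents in the JSON-lines span format
#'
#' One document per line:
#' `{"doc_id": ..., "sentences": [{"text": ..., "mentions": [...]}]}` with
#' 0-based inclusive `start`/`end` character offsets per mention.
#'
#' @param docs List of [annotated_document()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_docs_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    as.character(jsonlite::toJSON(doc_to_list(d), auto_unbox = TRUE))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read documents from the JSON-lines span format
#'
#' @param path Input file path written by [write_docs_jsonl()].
#' @return List of [annotated_document()] objects.
#' @export
read_docs_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    list_to_doc(jsonlite::fromJSON(ln, simplifyVector = FALSE))
  })
}
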