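#' BIO tag set for a set of entity types
#'
#' Tag order puts `"O"` first, then `B-T`/`I-T` per type in the given order.
#' Keeping `"O"` at index 1 makes the all-zero-score decode fall back to the
#' outside tag under the lowest-index tie-break rule.
#'
#' @param types Character vector of entity types.
#' @param scheme `"BIO"` (default) or `"BIOES"`.
#' @return Character vector of tags.
#' @export
tag_set <- function(types, scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  prefixes <- if (scheme == "BIO") c("B", "I") else c("B", "I", "E", "S")
  c("O", as.vector(t(outer(prefixes, types, paste, sep = "-"))))
}

#' Convert mention spans to a BIO tag sequence
#'
#' Emits one tag per token: `B-T` for the first token of a mention of type
#' `T`, `I-T` for subsequent tokens, `O` elsewhere. Mention boundaries are
#' assumed to coincide with token boundaries (the tokenizer forces splits at
#' mention boundaries); a mention that still crosses token boundaries is an
#' error.
#'
#' @param sent An [annotated_sentence()].
#' @param scheme `"BIO"` or `"BIOES"`.
#' @return Character vector of tags, one per token.
#' @export
spans_to_bio <- function(sent, scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(sent, "mnp_sentence"))
  tok <- sent$tokens
  tags <- rep("O", nrow(tok))
  men <- sent$mentions
  for (i in seq_len(nrow(men))) {
    idx <- which(tok$start >= men$start[i] & tok$end <= men$end[i])
    if (length(idx) == 0L ||
        tok$start[idx[1L]] != men$start[i] ||
        tok$end[idx[length(idx)]] != men$end[i]) {
      stop(sprintf("mention '%s' (%d,%d) does not align with token boundaries",
                   men$surface[i], men$start[i], men$end[i]))
    }
    tp <- men$etype[i]
    if (scheme == "BIO") {
      tags[idx] <- paste0("I-", tp)
      tags[idx[1L]] <- paste0("B-", tp)
    } else {
      if (length(idx) == 1L) {
        tags[idx] <- paste0("S-", tp)
      } else {
        tags[idx] <- paste0("I-", tp)
        tags[idx[1L]] <- paste0("B-", tp)
        tags[idx[length(idx)]] <- paste0("E-", tp)
      }
    }
  }
  tags
}

#' Recover mention spans from a BIO tag sequence
#'
#' Inverse of [spans_to_bio()]. Malformed sequences (an `I-T` opening a
#' sentence, or following `O` or a tag of a different type) are repaired by
#' promoting the dangling `I-` to `B-`; every repair is counted. BIOES input
#' is accepted by treating `E-` as `I-` and `S-` as `B-`.
#'
#' @param tags Character vector of BIO tags, one per token.
#' @param sent The [annotated_sentence()] the tags refer to (for token spans
#'   and surface extraction).
#' @return A list with `mentions` (data.frame `surface`, `etype`, `start`,
#'   `end`) and `repairs` (number of dangling-I promotions applied).
#' @export
bio_to_spans <- function(tags, sent) {
  stopifnot(inherits(sent, "mnp_sentence"),
            length(tags) == nrow(sent$tokens))
  tok <- sent$tokens
  repairs <- 0L
  # normalize BIOES to BIO
  tags <- sub("^S-", "B-", sub("^E-", "I-", tags))
  prev_type <- NA_character_
  rows <- list()
  cur <- NULL # list(etype, first_idx, last_idx)
  close_cur <- function() {
    if (is.null(cur)) return(invisible(NULL))
    st <- tok$start[cur$first]; en <- tok$end[cur$last]
    rows[[length(rows) + 1L]] <<- data.frame(
      surface = substr(sent$text, st + 1L, en + 1L),
      etype = cur$etype, start = st, end = en, stringsAsFactors = FALSE)
    cur <<- NULL
    invisible(NULL)
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      close_cur()
      prev_type <- NA_character_
      next
    }
    prefix <- substr(tg, 1L, 1L)
    tp <- substr(tg, 3L, nchar(tg))
    if (prefix == "I" && (is.null(cur) || cur$etype != tp)) {
      repairs <- repairs + 1L
      prefix <- "B"
    }
    if (prefix == "B") {
      close_cur()
      cur <- list(etype = tp, first = i, last = i)
    } else {
      cur$last <- i
    }
    prev_type <- tp
  }
  close_cur()
  mentions <- if (length(rows)) do.call(rbind, rows) else empty_mentions()
  list(mentions = mentions, repairs = repairs)
}
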