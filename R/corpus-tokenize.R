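# Punctuation split off token edges. Underscores and hyphens stay word-internal
# (molecular formulas "C_35_H_42_O_11_", ranges "J-Q"); so do en/em dashes.
.edge_punct <- c(".", ",", ";", ":", "!", "?", "(", ")", "[", "]", "{", "}",
                 "\"", "'", "“", "”", "‘", "’", "<", ">",
                 "%", "/")

#' Tokenize a normalized sentence
#'
#' Whitespace tokenization followed by splitting leading/trailing punctuation
#' characters off as separate tokens, with each token keeping its 0-based
#' inclusive character span in the sentence. Underscores and hyphens are kept
#' word-internal so molecular formulas and hyphenated names survive as single
#' tokens. If `mention_spans` is given (a data.frame with `start`/`end`
#' columns), any mention boundary that falls strictly inside a token forces an
#' additional split at that boundary, so that every mention boundary coincides
#' with a token boundary.
#'
#' @param text A single normalized sentence.
#' @param mention_spans Optional data.frame with 0-based inclusive `start` and
#'   `end` columns of known mentions; token splits are forced at these
#'   boundaries.
#' @return A data.frame with columns `token`, `start`, `end` (0-based
#'   inclusive code-point spans; `substr(text, start+1, end+1) == token`).
#' @export
tokenize <- function(text, mention_spans = NULL) {
  stopifnot(length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_space <- chars == " "
  n <- length(chars)
  runs <- rle(is_space)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  keep <- !runs$values
  starts <- starts[keep]; stops <- stops[keep]

  out_tok <- character(0); out_s <- integer(0); out_e <- integer(0)
  emit <- function(s, e) {
    if (e < s) return(invisible(NULL))
    # peel leading edge punctuation
    while (s < e && chars[s] %in% .edge_punct) {
      out_tok <<- c(out_tok, chars[s]); out_s <<- c(out_s, s); out_e <<- c(out_e, s)
      s <- s + 1L
    }
    # peel trailing edge punctuation (collect, then emit after core)
    tail_s <- integer(0)
    while (e > s && chars[e] %in% .edge_punct) {
      tail_s <- c(e, tail_s)
      e <- e - 1L
    }
    out_tok <<- c(out_tok, paste(chars[s:e], collapse = ""))
    out_s <<- c(out_s, s); out_e <<- c(out_e, e)
    for (p in tail_s) {
      out_tok <<- c(out_tok, chars[p]); out_s <<- c(out_s, p); out_e <<- c(out_e, p)
    }
    invisible(NULL)
  }
  for (k in seq_along(starts)) emit(starts[k], stops[k])

  tok <- data.frame(token = out_tok, start = out_s - 1L, end = out_e - 1L,
                    stringsAsFactors = FALSE)

  if (!is.null(mention_spans) && nrow(mention_spans) > 0L) {
    cuts <- sort(unique(c(mention_spans$start, mention_spans$end + 1L)))
    tok <- split_tokens_at(tok, text, cuts)
  }
  tok
}

# Force token boundaries at the given 0-based cut positions (a cut at c means
# "a token may not span positions c-1 and c").
split_tokens_at <- function(tok, text, cuts) {
  rows <- vector("list", nrow(tok))
  for (i in seq_len(nrow(tok))) {
    s <- tok$start[i]; e <- tok$end[i]
    inner <- cuts[cuts > s & cuts <= e]
    bounds <- c(s, inner, e + 1L)
    pieces <- lapply(seq_len(length(bounds) - 1L), function(k) {
      ps <- bounds[k]; pe <- bounds[k + 1L] - 1L
      data.frame(token = substr(text, ps + 1L, pe + 1L),
                 start = ps, end = pe, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, pieces)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
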