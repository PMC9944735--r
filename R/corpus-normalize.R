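#' Normalize raw literature text
#'
#' Strips Markdown-style emphasis markers (`**`, `*`), collapses runs of
#' whitespace (including newlines and tabs) to single spaces, and trims
#' leading/trailing whitespace. All other characters — Unicode dashes,
#' subscript underscores in molecular formulas, punctuation — are preserved
#' verbatim, so character offsets measured on the normalized text are stable.
#'
#' The function is total (never errors) and idempotent:
#' `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param raw Character vector of raw text.
#' @return Character vector of normalized text, same length as `raw`.
#' @examples
#' normalize_text("** *Culcita novaeguineae* **")
#' @export
normalize_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- enc2utf8(as.character(raw))
  x[is.na(x)] <- ""
  x <- gsub("*", "", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)
  trimws(x)
}

# Abbreviations that commonly precede a capital without ending a sentence.
.sentence_abbrev <- c(
  "sp", "spp", "cf", "aff", "var", "et", "al", "Prof", "Dr", "Fig", "Figs",
  "Tab", "No", "Nat", "Prod", "Chem", "Biol", "Mar", "J", "e.g", "i.e",
  LETTERS
)

#' Split normalized text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `?`, `!`) followed by
#' whitespace and an uppercase letter or digit. A stop-list of common
#' abbreviations from the natural products literature ("sp.", "Prof.",
#' journal-title fragments such as "J." / "Nat." / "Prod.", single initials)
#' blocks splits after those tokens. Splitting is deliberately conservative:
#' occasional imperfect splits are tolerated because downstream filtering
#' discards sentences without indexed entities or of unsuitable length.
#'
#' @param text A single normalized string (see [normalize_text()]).
#' @return Character vector of sentences, each already normalized.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  text <- normalize_text(text)
  if (!nzchar(text)) return(character(0))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- integer(0)
  i <- 1L
  while (i <= n - 2L) {
    if (chars[i] %in% c(".", "?", "!") && chars[i + 1L] == " " &&
        grepl("[[:upper:][:digit:]]", chars[i + 2L])) {
      # token immediately before the terminator
      j <- i - 1L
      while (j >= 1L && !chars[j] %in% c(" ")) j <- j - 1L
      prev <- paste(chars[(j + 1L):(i - 1L)], collapse = "")
      prev <- sub("[[:punct:]]+$", "", prev)
      if (!(prev %in% .sentence_abbrev)) cut_after <- c(cut_after, i)
    }
    i <- i + 1L
  }
  if (length(cut_after) == 0L) return(text)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  out <- vapply(seq_along(starts), function(k) {
    paste(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
  out <- trimws(out)
  out[nzchar(out)]
}

#' Locate a surface form in a sentence
#'
#' Returns the 0-based, inclusive character offsets (counted in Unicode code
#' points on the normalized text) of the `occurrence`-th match of `surface`
#' in `text`. Matching is case-insensitive by default, mirroring how entity
#' tables print a canonical casing ("Red alga") for in-text lowercase
#' mentions; the returned span always satisfies
#' `end - start + 1 == nchar(surface)`.
#'
#' @param text A single normalized sentence.
#' @param surface Surface form to locate.
#' @param occurrence Which match to return (1 = first).
#' @param ignore_case Case-insensitive matching (default `TRUE`).
#' @return Integer vector `c(start, end)`, 0-based inclusive.
#' @examples
#' locate_span("abc abc", "abc", 2) # c(4, 6)
#' @export
locate_span <- function(text, surface, occurrence = 1L, ignore_case = TRUE) {
  stopifnot(length(text) == 1L, length(surface) == 1L, occurrence >= 1L)
  if (!nzchar(surface)) stop("empty surface form")
  hits <- find_occurrences(text, surface, ignore_case = ignore_case)
  if (nrow(hits) < occurrence) {
    stop(sprintf("surface '%s' has %d occurrence(s) in text, requested #%d",
                 surface, nrow(hits), occurrence))
  }
  c(start = hits$start[occurrence], end = hits$end[occurrence])
}

# All matches of `surface` in `text` as a data.frame(start, end), 0-based
# inclusive code-point offsets. Literal (non-regex) matching.
find_occurrences <- function(text, surface, ignore_case = TRUE) {
  if (ignore_case) {
    m <- gregexpr(tolower(surface), tolower(text), fixed = TRUE)[[1]]
  } else {
    m <- gregexpr(surface, text, fixed = TRUE)[[1]]
  }
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- as.integer(m) - 1L
  data.frame(start = start, end = start + nchar(surface) - 1L)
}
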