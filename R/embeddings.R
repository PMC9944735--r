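# Word and character vocabularies. Index 1 is the padding symbol (its vector
# is pinned to zero), index 2 the unknown symbol; real entries start at 3.
.PAD <- 1L
.UNK <- 2L

#' Build word and character vocabularies from documents
#'
#' Word lookup is case-folded (character features carry casing information);
#' the character alphabet is taken from the observed text.
#'
#' @param docs List of [annotated_document()] objects.
#' @param min_count Minimum token frequency for a word to get its own vector.
#' @return List with `words` and `chars`, each a character vector (excluding
#'   the implicit padding/unknown symbols).
#' @export
build_vocab <- function(docs, min_count = 1L) {
  toks <- unlist(lapply(docs, function(d) {
    unlist(lapply(d$sentences, function(s) s$tokens$token))
  }))
  if (is.null(toks)) toks <- character(0)
  tab <- table(tolower(toks))
  # radix sort = C-locale byte order, so the vocabulary (and with it the
  # seeded parameter initialization) is identical across locales
  words <- sort(names(tab[tab >= min_count]), method = "radix")
  chars <- sort(unique(strsplit(paste(toks, collapse = ""), "")[[1]]),
                method = "radix")
  list(words = words, chars = chars)
}

word_id <- function(vocab_map, tokens) {
  idx <- vocab_map[tolower(tokens)]
  idx[is.na(idx)] <- .UNK
  unname(idx)
}

char_ids <- function(char_map, token) {
  cs <- strsplit(token, "", fixed = TRUE)[[1]]
  idx <- char_map[cs]
  idx[is.na(idx)] <- .UNK
  unname(idx)
}

#' Create an embedding table
#'
#' Rows 1 and 2 are the padding vector (all zeros, kept fixed) and the
#' unknown-token vector; known vocabulary entries follow.
#'
#' @param words Character vector of vocabulary entries.
#' @param d Embedding dimension.
#' @param init `"uniform"` random initialization or a prefilled matrix
#'   (`length(words) x d`) of vectors.
#' @param seed Seed for random initialization.
#' @return List with `map` (named index vector) and `E` (matrix
#'   `(length(words)+2) x d`).
#' @export
embedding_table <- function(words, d, init = "uniform", seed = 1L) {
  V <- length(words)
  if (is.matrix(init)) {
    stopifnot(nrow(init) == V, ncol(init) == d)
    E <- rbind(matrix(0, 2L, d), init)
    E <- with_seed(seed, {
      E[.UNK, ] <- stats::runif(d, -0.25, 0.25)
      E
    })
  } else {
    lim <- sqrt(3 / d)
    E <- with_seed(seed, {
      M <- matrix(stats::runif((V + 2L) * d, -lim, lim), V + 2L, d)
      M[.PAD, ] <- 0
      M
    })
  }
  map <- stats::setNames(seq_len(V) + 2L, tolower(words))
  list(map = map, E = E, d = d)
}

#' Load pretrained word vectors in the plain text format
#'
#' Reads the whitespace-delimited `word v1 v2 ... vd` format produced by
#' word2vec-style tools. An optional leading header line `"<count> <dim>"` is
#' skipped. Vectors for words outside `vocab` (when given) are dropped;
#' vocabulary words without a pretrained vector are initialized randomly.
#'
#' @param path Path to the vector file.
#' @param vocab Optional character vector restricting/ordering the
#'   vocabulary; defaults to the words present in the file.
#' @param seed Seed for the random fallback vectors.
#' @return An [embedding_table()].
#' @export
load_word_vectors <- function(path, vocab = NULL, seed = 1L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty vector file")
  first <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1L]
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop("malformed vector file: no vector components")
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (length(v) != d || anyNA(v)) stop("malformed vector line")
    v
  }, numeric(d)))
  if (is.null(vocab)) vocab <- words
  tab <- embedding_table(vocab, d, seed = seed)
  hit <- match(tolower(vocab), tolower(words))
  ok <- !is.na(hit)
  tab$E[which(ok) + 2L, ] <- vecs[hit[ok], , drop = FALSE]
  tab
}
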