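#' Configuration for the synthetic corpus generator
#'
#' The generator emulates preprocessed marine-natural-product literature:
#' short documents of isolation/collection/identification statements whose
#' entity mentions come verbatim from a typed lexicon, including documents
#' that repeat one ambiguous surface form across sentences with a single
#' consistent gold type (the situation a document-level attention layer is
#' meant to resolve).
#'
#' @param seed Integer seed; drives one documented PRNG stream with per-
#'   document sub-streams, so document `i` is identical regardless of
#'   `n_docs`.
#' @param n_docs Number of documents.
#' @param sentences_per_doc Inclusive integer range (length-2) of sentences
#'   per document.
#' @param entity_density Probability that a sentence of a regular document is
#'   rendered from an entity-bearing template rather than a no-entity filler
#'   template.
#' @param ambiguity_rate Fraction of documents built around a repeated
#'   ambiguous surface form (consistent gold type within the document).
#' @param types Entity types to generate (default [mnp_types()]).
#' @param full_types Keep the extended type inventory in the lexicon.
#' @return Object of class `mnp_generator_config`.
#' @export
generator_config <- function(seed = 42L, n_docs = 500L,
                             sentences_per_doc = c(3L, 8L),
                             entity_density = 0.8, ambiguity_rate = 0.3,
                             types = mnp_types(), full_types = FALSE) {
  stopifnot(length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1L,
            sentences_per_doc[1] <= sentences_per_doc[2],
            n_docs >= 0L)
  if (entity_density < 0 || entity_density > 1) {
    stop("entity_density must lie in [0, 1]: template slots cannot support a higher density")
  }
  if (ambiguity_rate < 0 || ambiguity_rate > 1) {
    stop("ambiguity_rate must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entity_density = entity_density,
                 ambiguity_rate = ambiguity_rate,
                 types = types, full_types = full_types),
            class = "mnp_generator_config")
}

# Entity-bearing sentence templates, shaped like the isolation/collection/
# identification statements of the worked examples. `{Type}` slots are filled
# from the lexicon; `{FILLER}` takes a non-entity compound-class word.
.entity_templates <- c(
  "{Bioactivity} {FILLER} were isolated from the {Sample_types} {Generic_name} {Specific_name}.",
  "{Compound_name} ({Formula}) was isolated from extracts of the {Sample_types} {Generic_name} {Specific_name}.",
  "{Generic_name} {Specific_name} was collected {Sample_source} and identified by specialists.",
  "Two new {FILLER} from the {Sample_types} {Generic_name} {Specific_name} showed {Bioactivity} activity.",
  "The {Sample_types} {Generic_name} {Specific_name} was collected {Sample_source} in May 2008.",
  "{Compound_name} exhibited {Bioactivity} activity against cultured tumor cell lines.",
  "Chemical investigation of {Generic_name} {Specific_name} afforded {Compound_name} with molecular formula {Formula}.",
  "Extracts of the {Sample_types} collected {Sample_source} yielded {Compound_name} and related {FILLER}.",
  "{Compound_name} and related metabolites from the {Sample_types} {Generic_name} showed {Bioactivity} effects."
)

.neutral_templates <- c(
  "The structures of the isolated {FILLER} were elucidated by NMR spectroscopy and mass spectral analyses.",
  "Voucher specimens were deposited in the herbarium collection for further study."
)

# Ambiguity-document frames. The anchor frame makes the type of the repeated
# surface locally unambiguous; the neutral frames do not.
.amb_anchor <- c(
  Compound_name = "{AMB} was isolated from the {Sample_types} {Generic_name} {Specific_name} and purified by chromatography.",
  Generic_name = "Fresh specimens of {AMB} were collected {Sample_source} and identified by taxonomists.")
.amb_neutral <- c(
  "Further chemical and biological studies of {AMB} are currently in progress.",
  "The unique properties of {AMB} have attracted considerable research interest.",
  "Previous reports on {AMB} prompted a detailed reinvestigation.")

# Render one template into an annotated sentence. `amb` (optional) is a
# list(surface, etype) filling the {AMB} slot. Sampling uses the RNG in scope.
render_template <- function(template, lexicon, amb = NULL) {
  m <- gregexpr("\\{[A-Za-z_]+\\}", template)[[1]]
  pieces <- character(0)
  pos <- 1L
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      if (m[k] > pos) {
        pieces <- c(pieces, substr(template, pos, m[k] - 1L))
      }
      pieces <- c(pieces, substr(template, m[k],
                                 m[k] + attr(m, "match.length")[k] - 1L))
      pos <- m[k] + attr(m, "match.length")[k]
    }
  }
  if (pos <= nchar(template)) {
    pieces <- c(pieces, substr(template, pos, nchar(template)))
  }
  text <- ""
  rows <- list()
  for (p in pieces) {
    if (startsWith(p, "{")) {
      slot <- substr(p, 2L, nchar(p) - 1L)
      if (slot == "FILLER") {
        text <- paste0(text, sample(lexicon$filler, 1L))
      } else if (slot == "AMB") {
        st <- nchar(text)
        text <- paste0(text, amb$surface)
        rows[[length(rows) + 1L]] <- data.frame(
          surface = amb$surface, etype = amb$etype,
          start = st, end = nchar(text) - 1L, stringsAsFactors = FALSE)
      } else {
        surf <- sample(lexicon$types[[slot]], 1L)
        st <- nchar(text)
        text <- paste0(text, surf)
        rows[[length(rows) + 1L]] <- data.frame(
          surface = surf, etype = slot,
          start = st, end = nchar(text) - 1L, stringsAsFactors = FALSE)
      }
    } else {
      text <- paste0(text, p)
    }
  }
  # sentence-initial capitalization; the stored surface keeps in-text casing
  first <- substr(text, 1L, 1L)
  if (first %in% letters) {
    text <- paste0(toupper(first), substr(text, 2L, nchar(text)))
    if (length(rows) && rows[[1L]]$start == 0L) {
      s <- rows[[1L]]$surface
      rows[[1L]]$surface <- paste0(toupper(substr(s, 1L, 1L)),
                                   substr(s, 2L, nchar(s)))
    }
  }
  mentions <- if (length(rows)) do.call(rbind, rows) else empty_mentions()
  annotated_sentence(text, mentions)
}

#' Generate a synthetic annotated corpus
#'
#' Renders `config$n_docs` documents from hand-written sentence templates.
#' A fraction `ambiguity_rate` of documents are ambiguity documents: they
#' repeat one surface form (usable as either compound or genus name) in
#' 2-3 sentences — one type-revealing anchor sentence and neutral frames —
#' with one consistent gold type, exercising document-level label
#' consistency. All gold offsets are exact by construction and satisfy the
#' corpus-module invariants. Fully deterministic under `config$seed`.
#'
#' @param config A [generator_config()].
#' @param lexicon Optional prebuilt [build_lexicon()] (rebuilt from `config`
#'   when omitted).
#' @return List with `docs` (list of [annotated_document()]) and `report`
#'   (ground truth bookkeeping: per-type mention counts, per-document
#'   sentence/entity counts, ambiguity document table).
#' @export
generate_corpus <- function(config = generator_config(), lexicon = NULL) {
  stopifnot(inherits(config, "mnp_generator_config"))
  if (is.null(lexicon)) lexicon <- build_lexicon(config)
  if (config$n_docs == 0L) {
    return(list(docs = list(),
                report = list(n_docs = 0L, counts = integer(0),
                              doc_stats = NULL, ambiguity = NULL)))
  }
  docs <- vector("list", config$n_docs)
  stats <- vector("list", config$n_docs)
  ambrows <- list()
  for (i in seq_len(config$n_docs)) {
    doc_id <- sprintf("synth%04d", i)
    res <- with_seed(derive_seed(config$seed, i), {
      is_amb <- stats::runif(1) < config$ambiguity_rate &&
        nrow(lexicon$ambiguous) > 0L
      n_s <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1L)
      if (is_amb) {
        n_s <- max(n_s, 3L)
        k <- sample(nrow(lexicon$ambiguous), 1L)
        amb <- list(surface = lexicon$ambiguous$surface[k],
                    etype = sample(lexicon$ambiguous$types[[k]], 1L))
        n_neutral <- sample(1:2, 1L)
        sents <- c(
          list(render_template(.amb_anchor[[amb$etype]], lexicon, amb)),
          lapply(sample(.amb_neutral, n_neutral),
                 render_template, lexicon = lexicon, amb = amb),
          lapply(seq_len(max(0L, n_s - 1L - n_neutral)), function(j) {
            render_template(sample(.entity_templates, 1L), lexicon)
          }))
      } else {
        amb <- NULL
        sents <- lapply(seq_len(n_s), function(j) {
          tmpl <- if (stats::runif(1) < config$entity_density) {
            sample(.entity_templates, 1L)
          } else {
            sample(.neutral_templates, 1L)
          }
          render_template(tmpl, lexicon)
        })
      }
      list(doc = annotated_document(doc_id, sents), amb = amb)
    })
    docs[[i]] <- res$doc
    n_ment <- vapply(res$doc$sentences, function(s) nrow(s$mentions), integer(1))
    stats[[i]] <- data.frame(doc_id = doc_id,
                             n_sentences = length(res$doc$sentences),
                             n_entity_sentences = sum(n_ment > 0L),
                             n_mentions = sum(n_ment),
                             ambiguity = !is.null(res$amb),
                             stringsAsFactors = FALSE)
    if (!is.null(res$amb)) {
      ambrows[[length(ambrows) + 1L]] <- data.frame(
        doc_id = doc_id, surface = res$amb$surface, etype = res$amb$etype,
        stringsAsFactors = FALSE)
    }
  }
  all_types <- unlist(lapply(docs, function(d) {
    unlist(lapply(d$sentences, function(s) s$mentions$etype))
  }))
  report <- list(
    n_docs = config$n_docs,
    counts = if (length(all_types)) table(all_types) else integer(0),
    doc_stats = do.call(rbind, stats),
    ambiguity = if (length(ambrows)) do.call(rbind, ambrows) else NULL)
  list(docs = docs, report = report)
}

#' Entity index derived from a lexicon
#'
#' Flattens the lexicon's typed surface pools (plus the ambiguous pool) into
#' an [entity_index()], as used when pairing raw preprocessed sentences with
#' known \verb{<entity, type>} pairs.
#'
#' @param lexicon A [build_lexicon()] result.
#' @param include_ambiguous Register ambiguous surfaces under both of their
#'   types.
#' @return An [entity_index()].
#' @export
lexicon_index <- function(lexicon, include_ambiguous = TRUE) {
  surfaces <- unlist(lexicon$types, use.names = FALSE)
  etypes <- rep(names(lexicon$types),
                vapply(lexicon$types, length, integer(1)))
  if (include_ambiguous && nrow(lexicon$ambiguous)) {
    for (k in seq_len(nrow(lexicon$ambiguous))) {
      surfaces <- c(surfaces, rep(lexicon$ambiguous$surface[k], 2L))
      etypes <- c(etypes, lexicon$ambiguous$types[[k]])
    }
  }
  entity_index(surfaces, etypes)
}

#' Split documents into train and test sets
#'
#' Document-disjoint split: a seeded shuffle assigns `round(fraction * n)`
#' documents (clamped so both sides are non-empty) to the training set. The
#' default fraction follows the roughly 5:1 train:test ratio conventional for
#' this kind of corpus.
#'
#' @param docs List of documents.
#' @param fraction Fraction of documents assigned to training.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` document lists.
#' @export
train_test_split <- function(docs, fraction = 5 / 6, seed = 1L) {
  n <- length(docs)
  if (n < 2L) stop("need at least 2 documents to split")
  stopifnot(fraction > 0, fraction < 1)
  n_train <- min(max(round(fraction * n), 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n))
  list(train = docs[sort(idx[seq_len(n_train)])],
       test = docs[sort(idx[(n_train + 1L):n])])
}
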