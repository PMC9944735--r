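test_that("normalize_text strips emphasis, collapses whitespace, is idempotent", {
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("a  b"), "a b")
  expect_equal(normalize_text("**bold** and *ital*  x"), "bold and ital x")
  expect_equal(normalize_text("  padded\t\ntext "), "padded text")
  # unicode dashes and formula underscores survive verbatim
  expect_equal(normalize_text("(1–8) C_35_H_42_O_11_"),
               "(1–8) C_35_H_42_O_11_")
  sents <- worked_sentences()
  for (s in sents) expect_identical(normalize_text(s), s)
})

test_that("worked-example mention offsets are recovered on normalized text", {
  sents <- worked_sentences()
  # frozen expected offsets for the verified example rows
  expect_equal(unname(locate_span(sents[1], "Cytotoxic")), c(0, 8))
  expect_equal(unname(locate_span(sents[1], "Culcita")), c(90, 96))
  expect_equal(unname(locate_span(sents[1], "novaeguineae")), c(98, 109))
  expect_equal(unname(locate_span(sents[2], "Hippasteria")), c(54, 64))
  expect_equal(unname(locate_span(sents[2], "kurilensis")), c(66, 75))
  expect_equal(unname(locate_span(sents[3], "red alga")), c(68, 75))
  expect_equal(unname(locate_span(sents[3], "Callophycus serratus")), c(77, 96))
  expect_equal(unname(locate_span(sents[5], "Polysiphonia urceolata")), c(0, 21))
  expect_equal(unname(locate_span(sents[5], "At the coast of Yantai, China")),
               c(37, 65))
  # every catalogued mention satisfies the offset convention
  for (ex in worked_examples()) {
    s <- normalize_text(ex$raw)
    for (i in seq_len(nrow(ex$mentions))) {
      sp <- locate_span(s, ex$mentions$surface[i])
      expect_equal(sp[["end"]] - sp[["start"]] + 1L,
                   nchar(ex$mentions$surface[i]))
    }
  }
})

test_that("locate_span handles occurrences, case policy, and absence", {
  expect_equal(unname(locate_span("abc", "abc")), c(0, 2))
  expect_equal(unname(locate_span("abc abc", "abc", occurrence = 2)), c(4, 6))
  expect_equal(unname(locate_span("The Red alga", "red alga")), c(4, 11))
  expect_error(locate_span("abc", "zzz"), "occurrence")
  expect_error(locate_span("abc abc", "abc", occurrence = 3), "occurrence")
})

test_that("sentence splitting respects abbreviations and terminators", {
  out <- split_sentences(
    "Compounds were isolated. They were assayed against bacteria.")
  expect_length(out, 2)
  expect_equal(out[1], "Compounds were isolated.")
  # 'Prof.' and genus 'sp.' do not end sentences
  out <- split_sentences(
    "It was identified by Prof. Xiao Fan. A voucher was kept.")
  expect_length(out, 2)
  out <- split_sentences("Siliquariaspongia sp. Was studied. Then assayed.")
  expect_length(out, 2)
  expect_equal(split_sentences(""), character(0))
})

test_that("tokenize produces span-consistent tokens and splits edge punctuation", {
  txt <- "Bromophycolides J-Q (1–8) were isolated."
  tok <- tokenize(txt)
  for (i in seq_len(nrow(tok))) {
    expect_identical(substr(txt, tok$start[i] + 1, tok$end[i] + 1),
                     tok$token[i])
  }
  expect_true(all(c("(", ")", ".") %in% tok$token))
  expect_true("J-Q" %in% tok$token)     # internal hyphen kept
  expect_true("1–8" %in% tok$token) # en dash kept word-internal
  # formulas with underscores survive as one token
  tok2 <- tokenize("Formula C_35_H_42_O_11_ reported.")
  expect_true("C_35_H_42_O_11_" %in% tok2$token)
  # a mention boundary inside a token forces a split
  txt3 <- "micro-algae bloom"
  tok3 <- tokenize(txt3, mention_spans = data.frame(start = 6L, end = 10L))
  expect_true(any(tok3$start == 6L))
  expect_true(any(tok3$end == 5L))
})

test_that("entity index stores pairs and resolves multi-type surfaces by priority", {
  idx <- entity_index(c("Culcita", "red alga", "halitoxin", "halitoxin"),
                      c("Generic_name", "Sample_types", "Compound_name",
                        "Generic_name"),
                      type_priority = c("Compound_name", "Generic_name"))
  expect_equal(nrow(idx$pairs), 4)
  expect_equal(index_types(idx, "halitoxin"),
               c("Compound_name", "Generic_name"))
  expect_equal(index_types(idx, "CULCITA"), "Generic_name")
  expect_equal(index_types(idx, "unknown"), character(0))
  expect_error(entity_index(character(0), character(0)), "at least one")
})

test_that("split_and_filter keeps entity sentences of suitable length", {
  idx <- entity_index("Culcita", "Generic_name")
  raw <- paste("Cytotoxic compounds were found in the starfish Culcita.",
               "The weather was nice that day in the harbour.")
  out <- split_and_filter(raw, idx)
  expect_length(out, 1)
  expect_match(out, "Culcita")
  expect_equal(split_and_filter("No entities here at all today.", idx),
               character(0))
  # length filter
  expect_equal(split_and_filter("Culcita.", idx, min_len = 5, max_len = 10),
               character(0))
})

test_that("split_and_filter retains exactly the generator's entity sentences", {
  gen <- tiny_corpus(n_docs = 30, seed = 11)
  lex <- build_lexicon(generator_config(seed = 11))
  idx <- lexicon_index(lex)
  for (i in seq_along(gen$docs)) {
    d <- gen$docs[[i]]
    raw <- paste(vapply(d$sentences, function(s) s$text, character(1)),
                 collapse = " ")
    kept <- split_and_filter(raw, idx, min_len = 5, max_len = 120)
    expect_length(kept, gen$report$doc_stats$n_entity_sentences[i])
  }
})

test_that("pair_entities recovers worked-example and synthetic mentions", {
  sents <- worked_sentences()
  idx <- entity_index(c("Red alga", "Laurencia similis",
                        "Sanya Bay, Hainan province"),
                      c("Sample_types", "Generic_name", "Sample_source"))
  res <- pair_entities(sents[4], idx, doc_id = "t2s4")
  men <- res$doc$sentences[[1]]$mentions
  # offsets recomputed on the normalized sentence via the locate_span oracle
  want <- do.call(rbind, lapply(
    c("red alga", "Laurencia similis", "Sanya Bay, Hainan province"),
    function(sf) {
      sp <- locate_span(sents[4], sf)
      data.frame(start = sp[["start"]], end = sp[["end"]])
    }))
  expect_equal(sort(men$start), sort(want$start))
  expect_equal(sort(men$end), sort(want$end))

  # no indexed surface -> no mentions
  res0 <- pair_entities("Nothing to see here.", idx)
  expect_equal(nrow(res0$doc$sentences[[1]]$mentions), 0)

  # synthetic corpus: recovered mentions equal generator ground truth
  # (ambiguity documents excluded: a pair index cannot decide their types)
  gen <- tiny_corpus(n_docs = 15, seed = 5, ambiguity_rate = 0)
  lex <- build_lexicon(generator_config(seed = 5))
  sidx <- lexicon_index(lex)
  for (d in gen$docs[1:8]) {
    texts <- vapply(d$sentences, function(s) s$text, character(1))
    res <- suppressWarnings(pair_entities(texts, sidx, doc_id = d$doc_id))
    for (s in seq_along(d$sentences)) {
      expect_same_mentions(res$doc$sentences[[s]]$mentions,
                           d$sentences[[s]]$mentions)
    }
  }
})

test_that("pair_entities resolves overlaps longest-match-first and reports ambiguity", {
  idx <- entity_index(c("red alga", "alga bloom", "halitoxin", "halitoxin"),
                      c("Sample_types", "Sample_types", "Compound_name",
                        "Generic_name"))
  res <- suppressWarnings(
    pair_entities("The red alga bloom produced halitoxin.", idx))
  men <- res$doc$sentences[[1]]$mentions
  # the longer candidate claims the overlapping characters first
  expect_true("alga bloom" %in% men$surface)
  expect_false("red alga" %in% men$surface)
  expect_equal(res$ambiguous$kept, "Compound_name")
  expect_match(res$ambiguous$alternatives, "Generic_name")
})

test_that("BIO conversion round-trips and repairs dangling I- tags", {
  s <- annotated_sentence("Plain words only here.")
  expect_equal(spans_to_bio(s), rep("O", nrow(s$tokens)))

  sents <- worked_sentences()
  s1 <- annotated_sentence(sents[1], data.frame(
    surface = "Cytotoxic", etype = "Bioactivity", start = 0L, end = 8L))
  tags <- spans_to_bio(s1)
  expect_equal(tags[1], "B-Bioactivity")
  expect_true(all(tags[-1] == "O"))

  # property: round-trip identity over generated sentences
  gen <- tiny_corpus(n_docs = 25, seed = 13)
  n_checked <- 0
  for (d in gen$docs) for (s in d$sentences) {
    rec <- bio_to_spans(spans_to_bio(s), s)
    expect_equal(rec$repairs, 0)
    expect_same_mentions(rec$mentions, s$mentions)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)

  # BIOES round trip
  for (d in gen$docs[1:5]) for (s in d$sentences) {
    rec <- bio_to_spans(spans_to_bio(s, scheme = "BIOES"), s)
    expect_same_mentions(rec$mentions, s$mentions)
  }

  # dangling I- is promoted to B- and counted
  s2 <- annotated_sentence("alpha beta gamma")
  rec <- bio_to_spans(c("I-Formula", "O", "I-Formula"), s2)
  expect_equal(rec$repairs, 2)
  expect_equal(rec$mentions$surface, c("alpha", "gamma"))
})

test_that("CoNLL I/O round-trips byte-identically and flags malformed input", {
  gen <- tiny_corpus(n_docs = 8, seed = 3)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_conll(gen$docs, f1)
  docs <- read_conll(f1)
  expect_length(docs, 8)
  expect_equal(attr(docs, "repairs"), 0)
  write_conll(docs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  # token and tag streams survive (sentence text is reconstructed by
  # joining tokens with spaces, so raw surfaces may differ in spacing)
  stream <- function(ds) unlist(lapply(ds, function(d) {
    lapply(d$sentences, function(s) {
      list(s$tokens$token, spans_to_bio(s))
    })
  }), recursive = TRUE)
  expect_identical(stream(docs), stream(gen$docs))

  # empty file -> no documents
  f3 <- withr::local_tempfile(lines = character(0))
  expect_length(read_conll(f3), 0)

  # malformed line -> parse error with line number
  f4 <- withr::local_tempfile(lines = c("-DOCSTART- d1", "", "token no tab"))
  expect_error(read_conll(f4), "line 3")

  # sentence-initial I- tag is repaired and logged
  f5 <- withr::local_tempfile(lines = c("-DOCSTART- d1", "",
                                        "tok\tI-Formula", ""))
  docs5 <- read_conll(f5)
  expect_equal(attr(docs5, "repairs"), 1)
  expect_equal(docs5[[1]]$sentences[[1]]$mentions$etype, "Formula")
})

test_that("JSON-lines span format round-trips exactly", {
  gen <- tiny_corpus(n_docs = 5, seed = 9)
  f <- withr::local_tempfile()
  write_docs_jsonl(gen$docs, f)
  back <- read_docs_jsonl(f)
  expect_length(back, 5)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$doc_id, gen$docs[[i]]$doc_id)
    for (s in seq_along(back[[i]]$sentences)) {
      expect_identical(back[[i]]$sentences[[s]]$text,
                       gen$docs[[i]]$sentences[[s]]$text)
      expect_same_mentions(back[[i]]$sentences[[s]]$mentions,
                           gen$docs[[i]]$sentences[[s]]$mentions)
    }
  }
})

test_that("annotated_sentence enforces the mention invariants", {
  expect_error(annotated_sentence("short", data.frame(
    surface = "toolong", etype = "X", start = 0L, end = 10L)), "bounds")
  expect_error(annotated_sentence("abcdef", data.frame(
    surface = "abc", etype = "X", start = 0L, end = 3L)), "length")
  expect_error(annotated_sentence("abcdef", data.frame(
    surface = "xyz", etype = "X", start = 0L, end = 2L)), "match")
  expect_error(annotated_sentence("abcdef", data.frame(
    surface = c("abcd", "cdef"), etype = "X", start = c(0L, 2L),
    end = c(3L, 5L))), "overlap")
})
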