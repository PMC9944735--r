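# Shared fixtures: a small encoder configuration for fast model tests and a
# tiny deterministic corpus.

small_enc <- function(...) {
  encoder_config(d_w = 8L, d_char = 5L, d_char_feat = 6L, filters = 10L,
                 blocks = 2L, dropout = 0, ...)
}

tiny_corpus <- function(n_docs = 6L, seed = 7L, ...) {
  generate_corpus(generator_config(seed = seed, n_docs = n_docs, ...))
}

# Normalized worked-example sentences, in table order.
worked_sentences <- function() {
  vapply(worked_examples(), function(ex) normalize_text(ex$raw), character(1))
}

expect_same_mentions <- function(got, want) {
  cols <- c("surface", "etype", "start", "end")
  got <- got[do.call(order, got[c("start", "end")]), cols, drop = FALSE]
  want <- want[do.call(order, want[c("start", "end")]), cols, drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
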