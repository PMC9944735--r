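---
title: "Methods: attention-augmented dilated-convolution CRF tagging for marine natural product literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-augmented dilated-convolution CRF tagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task

Marine natural product (MNP) research mines its primary literature for
structured facts: which compound, with which molecular formula, was isolated
from which organism, collected where, with what bioactivity. `mnpner`
implements the full chain from raw literature text to typed character-level
entity spans: corpus construction, a synthetic annotated-corpus generator, a
neural sequence tagger (word + character features, iterated dilated
convolutions, document-level attention) over a linear-chain conditional
random field, and an exact-match evaluation protocol.

A specific failure mode motivates the model: sentence-level taggers label
each sentence in isolation, so a surface form repeated across a document can
receive conflicting types — "label inconsistency". The attention layer gives
every token a document-wide context vector so that one type-revealing
sentence can disambiguate the other occurrences.

## Corpus conventions

*Offsets.* Character offsets are 0-based and inclusive at both ends, counted
in Unicode code points on the *normalized* sentence, so every mention
satisfies `end - start + 1 == nchar(surface)`. Normalization strips
Markdown-style emphasis markers (`**`, `*`), collapses whitespace runs and
trims; everything else (en dashes, formula underscores) is preserved so that
offsets are stable.

*Case.* Mention matching is case-insensitive — entity tables conventionally
print a canonical casing ("Red alga") for in-text lowercase mentions — and
the stored surface keeps the in-text casing.

*Tokenization.* Whitespace split, then leading/trailing punctuation split
off as separate tokens. Underscores and hyphens stay word-internal so
`C_35_H_42_O_11_` and `J-Q` survive as single tokens. A mention boundary
falling inside a token forces an additional split, so BIO tags can always
express the gold spans exactly.

*Sentence splitting* is deliberately conservative (split on `.?!` +
whitespace + uppercase/digit, with an abbreviation stop-list: `sp.`,
`Prof.`, journal-title fragments, single initials). Imperfect splits are
tolerated because downstream filtering keeps only sentences that contain an
indexed entity and have 5–120 tokens.

*Entity pairing.* Known `<entity, type>` pairs form an index; every indexed
surface occurrence in a retained sentence becomes a mention. Overlapping
candidates are resolved longest-match-first, then left-to-right. A surface
registered under several types keeps the first type of a configured priority
order, and the alternatives are reported — the pair index itself carries no
disambiguation rule, which is precisely the ambiguity the tagger is for.

*Formats.* CoNLL-style `token<TAB>tag` files (blank-line sentence breaks,
`-DOCSTART-` document separators) and a JSON-lines span format (one document
per line with sentence text and typed mentions). The BIO scheme is the
default; BIOES is available behind a flag. Malformed BIO input (a dangling
`I-`) is repaired by promotion to `B-` and counted.

## The model

Each token is represented as the concatenation of a word vector (case-folded
lookup; out-of-vocabulary tokens share an unknown vector) and character
features (a width-3 character convolution, ReLU, max-pooled per token).
Character features are what generalize to unseen molecular formulas and
latinate species names.

The encoder applies two regular width-3 convolutions and then iterates a
shared dilated block (dilations 1, 1, 2) four times. The receptive field of
a stack of width-`w`, dilation-`d` convolutions grows by `(w-1)·d` per
layer, i.e. `1 + Σ (w-1)·d` overall — 37 tokens for the default stack, ample
for single sentences. Convolutions use same-padding, so sequence length is
preserved everywhere.

The attention layer scores every ordered token pair of the *document* with
the alignment function `f(x_i, x_j) = tanh(m_a·x_i + m_b·x_j)` (a weight
vector over the concatenation `[x_i; x_j]`), normalizes each row with a
softmax over the document's positions (capped at `max_doc_len`, default 512,
with positions beyond the cap masked), and forms context vectors
`v_i = Σ_j s_ij q_j` from the convolutional features `q`. The attention
output pairs each token's context with its own feature,
`p_i = tanh(M_v [v_i; q_i] + b_v)`, and per-token tag scores are a learned
affine projection with a final tanh, `e_i = tanh(W_e p_i + b_e)`. Two
interpretive choices deserve note: the attention output must pair `v_i` with
`q_i` (the only reading that yields one output per token), and the tag-score
layer cannot literally consume the N×N similarity matrix alongside a
fixed-width `p_i`, so it is implemented as the affine projection above.
Since `tanh` is bounded, every emission lies in (-1, 1).

The CRF scores a tag path as emissions plus transitions with explicit START
and STOP states; a document's score sums its per-sentence chain scores, and
decoding is per sentence (transitions never cross sentence boundaries — the
cross-sentence information flows through attention, not through the chain).
All inference is exact and in log space with 64-bit accumulation: the
forward recursion for the partition function, forward–backward marginals for
the training gradient, Viterbi for decoding with ties broken toward the
lowest tag index at every backtrack step (the `O` tag is index 1, so the
all-zero model decodes to all-`O`). A brute-force enumerator with the same
tie-break serves as the test oracle. Invalid-BIO transitions are *not*
masked by default (decoder output is repaired instead); a transition matrix
with hard constraints can be supplied by the user.

## Training

The objective is the mean per-sentence negative log-likelihood, minimized by
minibatch Adam (default learning rate 1e-3, 8 documents per batch) with
global gradient-norm clipping at 5.0 and optional early stopping on dev F
(patience 5). Runs are exactly reproducible under a single seed: parameter
initialization, shuffling and dropout all draw from one seeded stream, and
the vocabulary is ordered byte-wise (radix sort) so results do not depend on
the locale.

Two training dynamics shaped the defaults:

* **Depth versus initialization.** With Glorot initialization the 14-layer
  ReLU convolution stack attenuates its input roughly geometrically and the
  encoder output starts near zero; He-uniform initialization (variance
  `2/fan-in`) keeps the signal O(1) through the stack and is used for all
  convolution layers.
* **Bounded emissions saturate.** Because emissions pass through tanh, the
  majority class (`O`) saturates at +1 early, and its near-zero gradient
  makes the first epochs look inert before the encoder features
  differentiate and decoding snaps into place. This is a property of the
  bounded score layer, not a defect of the gradients (which are verified
  against finite differences to 1e-4); budgets below allow for it.

Default sizes (word vectors 50, character embeddings 16 with 16 pooled
features, 64 filters, dropout 0.2 on block outputs) are sized for
desk-scale corpora — they train the 500-document benchmark end to end in a
few minutes on one CPU and saturate its accuracy; all dimensions scale up by
configuration for larger corpora.

## The synthetic corpus

The generator emulates preprocessed MNP literature at the structural level:
short documents of isolation / collection / identification statements
rendered from ~10 hand-written templates, with slots filled from a typed
lexicon (curated seed surfaces — formulas, genera, epithets, sample types
and sources, bioactivities, compound names — plus seeded programmatic
expansions such as random `C_x_H_y_...` formulas and latinate binomials).
Gold offsets are exact by construction and are verified against the
corpus-module invariants in tests. A single integer seed drives per-document
sub-streams, so document *i* is identical regardless of how many documents
are generated.

A configurable fraction of documents are *ambiguity documents*: one surface
form registered as both a compound name and a genus name appears in 2–3
sentences — one type-revealing anchor sentence plus neutral frames — with a
single consistent gold type. The neutral frames are identical across the two
document types, so the surface's type is undecidable from the sentence
alone; a sentence-level model is structurally limited to the ~50% coin-flip
consistency on these, while the attention variant can propagate the anchor.

What the generator does **not** emulate: real linguistic variability,
abbreviation noise, nested or discontinuous mentions, out-of-template
syntax, or realistic sentence-length and entity-density distributions (the
literature does not characterize them; defaults are 3–8 sentences per
document and an 80% entity-template rate). Passing the end-to-end tests
therefore demonstrates that the implementation learns and decodes correctly
at realistic scale — not that the reported accuracies transfer to real
abstracts.

## Evaluation protocol

Exact-match counting: a prediction is a true positive only when entity type
and both character boundaries match a gold mention; any other prediction is
a false positive, and an unmatched gold mention is a false negative (a
wrong-boundary prediction counts once as FP and leaves its gold as FN).
True negatives are counted at sentence granularity (sentences with no gold
and no predicted mentions) and do not enter precision/recall/F, which are
reported ×100. Matching is by position, never by surface identity. The
speed metric (mean wall-clock seconds per training epoch) is reported but
excluded from every correctness assertion — it is hardware-dependent.

Label consistency of a document's predictions is the fraction of repeated
predicted surface forms (case-folded, ≥2 occurrences) whose predicted types
all agree; documents without repeats are excluded.

## Benchmark configurations

* **Capability floor.** Seed-42 corpus of 500 documents, 5:1
  train:test split, attention variant, default encoder, 20 epochs — span F
  on the held-out documents is required to reach at least 85 (×100 scale).
  This is a floor demonstrating end-to-end capability, not a reproduction of
  published scores (the underlying published dataset is not public).
* **Consistency comparison.** Ten replicate seeds; per seed a 150-document
  ambiguity-heavy corpus (3–4 sentences per document, ambiguity rate 0.7,
  every sentence entity-bearing), both variants trained for 30 epochs with
  batch size 4 and a reduced encoder (32 filters, 2 block iterations —
  the comparison is architectural, and the smaller stack trains each of the
  20 fits in under a minute). Consistency is measured on predictions over
  all 150 documents to cut estimator variance. The attention variant is
  required to match or beat the plain variant in at least 7 of 10 seeds.

## Known limitations

* Training is pure R; it is comfortable at the desk scale above but not
  meant for corpus sizes in the tens of thousands of documents.
* The bounded tanh emission layer caps per-token score margins; confidence
  never concentrates fully, and the early training epochs are slow (see
  above). The CRF transitions, which are unbounded, carry part of the
  discrimination.
* Sentence-splitting and tokenization are heuristic; their errors are
  tolerated by design rather than modeled.
* The attention layer is quadratic in document length; documents are capped
  at 512 attended positions by default.
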