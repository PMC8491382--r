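---
title: "Methods: disease co-mention networks, normalization and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease co-mention networks, normalization and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddaminer)
```

## The pipeline

`ddaminer` implements the two-step annotation pipeline standard in
biomedical text mining — named entity recognition (NER) followed by named
entity normalization (NEN) — and builds disease–disease association (DDA)
networks on top of its output.

The unit of analysis is a document: a title plus an abstract. All character
offsets index the composition `title + " " + abstract` (0-based, half-open),
the convention of the PubTator corpus format. Whether titles and abstracts
should be concatenated or processed separately before recognition is not
settled usage; this package asserts the concatenation convention because it
makes every offset check an exact string-slice comparison, and because
co-mention counting treats title and abstract as one bag anyway.

### Recognition

The built-in recognizer is a dictionary longest-match tagger: documents are
tokenized into maximal alphanumeric runs, and a greedy left-to-right scan
tries token n-grams (longest first, up to `max_ngram = 10` tokens, capped by
the longest term actually in the lexicon) against the lexicon's normalized
term index. A hit emits a mention and the scan resumes after it, so output
mentions never overlap. Token-boundary anchoring prevents partial-word hits
("oma" never fires inside "lymphoma"). The engine is deliberately simple:
it is deterministic, exactly analyzable, and recovers planted mentions
perfectly when the lexicon equals the generator vocabulary — which is what
makes the end-to-end oracle tests possible. Learned taggers (BioBERT-class
models) are supported as plug-ins through the recognizer contract
(`validate_recognizer_output()`): anything mapping documents to a valid,
sorted, non-overlapping mention table can replace the built-in engine. No
decoding conventions are imposed on plug-ins beyond that contract.

### Normalization

`normalize_term()` defines the lookup key: NFKC compatibility normalization
with case folding, punctuation runs replaced by single spaces (preserving
token boundaries in hyphenated names like "graft-versus-host disease"),
whitespace collapsed. Normalization of mention surfaces is exact-match
lookup under this key. Three deliberate choices:

- **Unknown sink.** A surface with no lexicon hit maps to the sentinel
  `UNKNOWN` rather than being dropped. Unknowns are counted in the corpus
  summary, never earn evaluation credit, and never enter DDA edges.
- **Deterministic collision tie-break.** A term indexed under several
  concepts resolves to the lexicographically smallest canonical identifier
  (`MESH:...` before `OMIM:...`). How MeSH/OMIM conflicts should be resolved
  is genuinely open; canonical-order tie-breaking is this package's own
  choice, made for reproducibility — a learned ranker could be layered on
  top via the plug-in route.
- **No fuzzy matching in the baseline.** Approximate matching would
  introduce score thresholds and non-determinism into the acceptance
  surface; exact matching keeps every downstream number reproducible.

### Evaluation

`metrics_from_counts()` applies the standard formulas
P = tp/(tp+fp), R = tp/(tp+fn), F1 = 2PR/(P+R), with the zero-denominator
convention that an undefined ratio is 0. Span-level NER scoring counts a
predicted mention as a true positive iff an unmatched gold mention in the
same document has the identical `(start, end)` span, one-to-one. Exact
boundary matching (no overlap credit) is the strict convention of the
community evaluation kits for disease NER, and the only one that makes
results fully deterministic; the test suite verifies it against an
exhaustive matching enumeration on hundreds of random small corpora.

Concept-level NEN scoring operates on per-document sets of distinct
non-`UNKNOWN` concept identifiers (set intersection/differences summed over
documents), in two modes: `gold_spans` re-normalizes the gold surfaces to
isolate normalization quality from recognition, and `predicted_spans`
scores the full pipeline so recognition errors cascade into the concept
score. Scoring granularity for such kits is not standardized; the
per-document distinct-set convention was chosen because co-mention analysis
downstream is itself per-document and set-valued. Published two-decimal
scores are compared with half-up rounding (`round_half_up()`), the rounding
used by most result tables, rather than banker's rounding.

## DDA networks

Two diseases are co-mentioned when both appear (as distinct, non-`UNKNOWN`
normalized concepts) in the same document. Counting is at **document
granularity**: a pair contributes at most once per document regardless of
mention multiplicity, because the association evidence is "they appear in
the same title/abstract", not "they appear near each other often".
Occurrence-weighted counting is available behind `count_mode =
"occurrence"`. Self-pairs are excluded: a mention normalizing to a target
concept itself (e.g. a "childhood leukemia" synonym resolving to the
leukemia descriptor) creates no edge.

`rank_and_filter()` mirrors the common presentation of target-focused DDA
studies: keep edges joining exactly one target disease to a partner
(target–target edges are reported separately), keep partners linked to at
least `min_target_links = 2` distinct targets, rank by support descending
and return the top `k = 100`. Whether "top 100" should rank edges or
partner diseases is ambiguous in practice; both are exposed
(`rank_by = "edges"` is the default). All ties break on the canonical pair
rendering so repeated runs are byte-identical.

The cancer/non-cancer split used when profiling a network's biology is an
ontology-backed proxy: a node is cancerous iff any of its MeSH tree numbers
starts with a configurable prefix (default `C04`, Neoplasms). Nodes without
tree numbers are reported as unclassified rather than silently binned.

Gene-overlap DDAs (the DisGeNET-style counterpart) relate a target to any
disease sharing at least `min_shared = 20` genes (inclusive threshold), with
the Jaccard index of the two gene sets as edge support. Network agreement
(`compare_dda_sets()`) matches edges on unordered concept pairs only,
ignoring supports and sources, optionally translating one network's
identifiers through a UMLS CUI map first; untranslatable edges are excluded
and counted. The recovered/unique fractions it reports are exactly the
statistics used to compare a text-mined network against a gene-centric one.
With an empty second network the recovered fraction is defined as 1 (with a
warning): vacuous recovery, flagged rather than undefined.

## The synthetic-data generators

The generators exist so that every claim in the test suite is checked
against constructed ground truth:

- `generate_lexicon()` builds pronounceable multi-token disease names with
  unique normalized forms (collisions only on request), MeSH-style
  identifiers and tree numbers placing 30% of concepts under `C04` by
  default — enough structure to exercise normalization, partitioning and
  XML round-trips.
- `generate_corpus()` plants surface forms at recorded offsets between
  digit-bearing filler tokens (filler can never match a lexicon term, and
  planted surfaces always sit on token boundaries), and bookkeeps
  per-pair document-level co-mention counts directly from the planted
  concept sets. Defaults — 3 planted mentions per document on average
  (Poisson), a 50% chance that a document includes 1–3 target diseases —
  emulate a query-retrieved corpus in which target diseases are frequent
  and co-occur with a moderate number of partners per abstract, the regime
  a disease-focused PubMed query produces.
- `corrupt_annotations()` degrades gold annotations with independent
  per-mention error rates (deletions `fn_rate`, insertions `fp_rate`,
  boundary jitter, concept swaps), so measured precision/recall have
  analytic expectations: E[R] = 1 − fn_rate and
  E[P] = (1 − fn_rate)/(1 − fn_rate + fp_rate).
- `generate_gene_sets()` realizes requested pairwise gene-set intersections
  exactly (pair-private shared blocks plus private padding, no gene in more
  than two sets), making threshold and Jaccard arithmetic checkable in
  closed form.

All generators take an explicit seed and restore the caller's RNG state;
there is no hidden global randomness.

What the generators do **not** emulate: natural language (filler is
non-linguistic, so tokenizer robustness to real prose is tested separately
with adversarial strings, not by the generator), abbreviations and
coordination ("B- and T-cell lymphomas"), nested or discontinuous mentions,
ambiguity resolvable only from context, publication-volume bias in
co-mention counts, and the long-tailed degree distributions of real
literature networks. Passing the synthetic suites therefore demonstrates
that the bookkeeping, scoring and network algebra are exact — not that the
dictionary baseline approaches transformer-grade recognition on real text.

## Problem sizes and numerical choices

The test and acceptance workloads use corpora of 60–1000 documents with
lexicons of 8–30 concepts, and calibration corpora of ~700 documents
(≥ 2000 gold mentions), sizes at which binomial sampling error on a rate of
0.8 is below 1% and every suite completes quickly. Calibration checks use
3-standard-deviation binomial bands around the analytic expectations.
Everything else in the package is exact and deterministic, so tests assert
equality, not tolerances: support counts are integers, ranking ties break
canonically, exports are byte-stable, and repeated pipeline runs must be
byte-identical.

Degenerate inputs are defined, not errors: empty corpora annotate to empty
mention tables; empty edge lists export valid (empty) documents;
`jaccard()` of two empty sets is 0; a document with a single concept
mentioned many times contributes no pairs. Inputs are treated as given —
no Unicode re-normalization happens at I/O time (it would shift offsets);
normalization happens only inside lexicon lookup.

## Limitations

- The dictionary recognizer cannot find surface forms absent from the
  lexicon; its recall on real text is bounded by lexicon coverage. It is a
  baseline and a reference implementation of the contract, not a substitute
  for a learned tagger on real corpora.
- Exact-match normalization misses morphological variants not present as
  synonyms; the collision tie-break is canonical-order, not context-aware.
- Co-mention support is raw document counts; no significance testing
  (e.g. hypergeometric enrichment) is applied, matching the ranking-by-count
  convention of co-mention DDA studies.
- MeSH parsing covers the descriptor/supplementary subset needed for names,
  synonyms and tree numbers; qualifier and pharmacological-action files
  contribute synonyms only.
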