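# ddaminer

Disease–disease association (DDA) mining from biomedical abstracts.

Knowledge about how diseases relate to one another is scattered across the
literature. One way to centralize it is text mining: recognize disease
mentions in titles and abstracts (NER), normalize each mention to a concept
in a controlled vocabulary such as MeSH or OMIM (NEN), and then declare two
diseases associated when they are **co-mentioned** — both appear in the same
title/abstract. Ranking pairs by how many documents co-mention them yields a
DDA network that can be compared against gene-centric resources (DisGeNET
style), where two diseases are associated when their gene lists share at
least a threshold number of genes, ranked by the Jaccard index
*J(A, B) = |A ∩ B| / |A ∪ B|*.

`ddaminer` is a toolkit for building and evaluating such pipelines:

- **Corpus I/O** — PubTator-format annotated corpora (`id|t|`, `id|a|` lines
  plus tab-separated mention lines with 0-based half-open offsets into
  `title + " " + abstract`) and plain abstract tables (TSV/CSV with
  `id`, `title`, `abstract`).
- **Lexicon** — disease concept lexicons from MeSH-schema descriptor XML
  (`DescriptorUI`, `TreeNumberList`, `ConceptList/TermList`) or plain term
  tables; UMLS CUI → MeSH/OMIM identifier translation.
- **NER** — a deterministic dictionary longest-match recognizer anchored to
  token boundaries. Any component producing a valid mention table (for
  example a transformer tagger) can be plugged in instead; the dictionary
  engine is the reproducible built-in.
- **NEN** — exact normalized-term lookup with a deterministic tie-break and
  an explicit `UNKNOWN` sink for surfaces absent from the lexicon.
- **Evaluation** — precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and the
  harmonic-mean F1 at exact-span level (NER) and per-document
  distinct-concept level (NEN), the latter either on gold spans ("given a
  perfect NER") or on predicted spans (recognition errors cascade).
- **DDA networks** — document-level co-mention aggregation, target-focused
  ranking (top-k edges linked to ≥ 2 target diseases), cancer/non-cancer
  partition by MeSH tree prefix (`C04`), edge-list TSV and GraphML export.
- **Comparison** — gene-overlap DDAs at a shared-gene threshold
  (≥ 20 by default) ranked by Jaccard, and recovered/unique fractions
  between two DDA networks.
- **Synthetic fixtures** — generators for every input kind with exact
  ground truth (planted mentions, known pair counts, exact gene-set
  overlaps, controlled corruption rates), so the whole pipeline is testable
  without any download.

Everything is tidyverse-native: tibbles in, tibbles out, `tidy()`/`glance()`
methods on results, `autoplot()` for quick figures.

## Worked example

```r
library(ddaminer)

lexicon <- build_lexicon(read_lexicon_table(paste(
  "concept_id\tpreferred_name\tsynonyms\ttree_numbers",
  "MESH:D007938\tLeukemia\tleukaemia\tC04.557.337",
  "MESH:D008223\tLymphoma\tlymphomas\tC04.557.386",
  "MESH:D009101\tMultiple Myeloma\tmyeloma|plasma cell myeloma\tC04.557.595",
  "MESH:D000740\tAnemia\tanaemia\tC15.378.071",
  "MESH:D005334\tFever\tpyrexia\tC23.888.119",
  sep = "\n")))

docs <- read_abstract_table(paste(
  "id\ttitle\tabstract",
  "101\tFever of unknown origin\tWe report fever preceding lymphoma and leukemia.",
  "102\tMyeloma case series\tMultiple myeloma with anemia was frequent; plasma cell myeloma follow-up.",
  "103\tLeukemia and anemia\tAnaemia accompanied leukemia in this cohort.",
  sep = "\n"))

ann <- annotate_corpus(docs, lexicon)
ann$summary
#>   n_documents n_skipped n_mentions n_unknown unknown_rate
#> 1           3         0         12         0            0
```

Twelve mentions are recognized and normalized, e.g. for document 102:

```r
ann$mentions[ann$mentions$doc_id == "102", c("start", "end", "surface", "concept_id")]
#>   start   end surface             concept_id
#> 1     0     7 Myeloma             MESH:D009101
#> 2    20    36 Multiple myeloma    MESH:D009101
#> 3    42    48 anemia              MESH:D000740
#> 4    63    82 plasma cell myeloma MESH:D009101
```

Offsets index the composed `title + " " + abstract` text; the three myeloma
surfaces all normalize to the same descriptor, so document 102 contributes
exactly one co-mention pair (myeloma–anemia). Aggregating:

```r
edges <- aggregate_comentions(ann$mentions)
edges[, 1:5]
#>   concept_a    concept_b    support source    n_docs
#> 1 MESH:D000740 MESH:D007938       1 comention      1
#> 2 MESH:D000740 MESH:D009101       1 comention      1
#> 3 MESH:D005334 MESH:D007938       1 comention      1
#> 4 MESH:D005334 MESH:D008223       1 comention      1
#> 5 MESH:D007938 MESH:D008223       1 comention      1
```

Each edge's `support` is the number of documents co-mentioning the pair.
Nodes partition into cancerous and non-cancerous by MeSH tree prefix:

```r
partition_by_tree(unique(c(edges$concept_a, edges$concept_b)), lexicon)
#>   concept_id   class
#> 1 MESH:D000740 non_cancerous   # anemia
#> 2 MESH:D005334 non_cancerous   # fever
#> 3 MESH:D007938 cancerous
#> 4 MESH:D009101 cancerous
#> 5 MESH:D008223 cancerous
```

From here, `rank_and_filter(edges, targets, k = 100)` keeps the strongest
partner edges linked to at least two target diseases, `genelist_ddas()`
builds the gene-overlap counterpart from a disease–gene table, and
`compare_dda_sets()` reports how much of one network the other recovers.

A command-line interface with subcommands `annotate`, `evaluate`, `ddas`,
`compare`, `synth` and `run` is available via `inst/cli/ddaminer.R`.

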