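# All generators take an explicit seed and leave the caller's RNG state
# untouched.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

syllables <- c(
  "ba", "ce", "di", "fo", "gu", "ha", "ke", "li", "mo", "nu",
  "pa", "re", "si", "to", "vu", "za", "bre", "clo", "dra", "fle"
)

pronounceable_word <- function(n_syll) {
  paste(sample(syllables, n_syll, replace = TRUE), collapse = "")
}

#' Generate a synthetic disease lexicon with known ground truth
#'
#' Produces unique, pronounceable multi-token disease names (so that
#' normalized terms never collide across concepts unless collisions are
#' requested), MeSH-style identifiers, optional synonyms per concept, and
#' tree numbers placing a fraction of concepts under the Neoplasms branch
#' (`C04`) and the rest elsewhere in the disease tree.
#'
#' @param n_concepts Number of concepts (>= 1).
#' @param synonyms_per_concept Synonyms per concept besides the preferred
#'   name (default 2).
#' @param seed Integer seed (required).
#' @param cancer_fraction Fraction of concepts tagged with a `C04` tree
#'   number (default 0.3; applied to the first
#'   `round(cancer_fraction * n_concepts)` concepts).
#' @param n_collisions Number of extra shared synonyms planted across
#'   concept pairs to exercise collision handling (default 0).
#' @return Entries tibble for [build_lexicon()].
#' @export
generate_lexicon <- function(n_concepts, synonyms_per_concept = 2, seed,
                             cancer_fraction = 0.3, n_collisions = 0) {
  stopifnot(n_concepts >= 1)
  with_local_seed(seed, {
    n_names <- n_concepts * (1 + synonyms_per_concept)
    names_pool <- character(0)
    while (length(names_pool) < n_names) {
      cand <- vapply(seq_len(n_names * 2), function(i) {
        paste(
          vapply(seq_len(sample(2:3, 1)), function(j) {
            pronounceable_word(sample(2:3, 1))
          }, ""),
          collapse = " "
        )
      }, "")
      names_pool <- unique(c(names_pool, cand))
    }
    names_pool <- names_pool[seq_len(n_names)]
    n_cancer <- round(cancer_fraction * n_concepts)
    entries <- tibble(
      concept_id = sprintf("MESH:D9%05d", seq_len(n_concepts)),
      preferred_name = stringr::str_to_title(names_pool[seq_len(n_concepts)]),
      synonyms = lapply(seq_len(n_concepts), function(i) {
        if (synonyms_per_concept == 0) return(character())
        idx <- n_concepts + (i - 1) * synonyms_per_concept +
          seq_len(synonyms_per_concept)
        names_pool[idx]
      }),
      tree_numbers = lapply(seq_len(n_concepts), function(i) {
        if (i <= n_cancer) {
          sprintf("C04.%03d", i)
        } else {
          sprintf("C%02d.%03d", 5 + (i %% 15), i)
        }
      })
    )
    if (n_collisions > 0) {
      if (n_concepts < 2) {
        abort_ddaminer("collisions need >= 2 concepts", "ddaminer_domain_error")
      }
      for (k in seq_len(n_collisions)) {
        pair <- sample(n_concepts, 2)
        shared <- paste(pronounceable_word(3), pronounceable_word(2), "syndrome")
        entries$synonyms[[pair[1]]] <- c(entries$synonyms[[pair[1]]], shared)
        entries$synonyms[[pair[2]]] <- c(entries$synonyms[[pair[2]]], shared)
      }
    }
    entries
  })
}

#' Serialize lexicon entries as MeSH-schema descriptor XML
#'
#' Writes a `DescriptorRecordSet` document in the descriptor-record
#' schema subset read by [parse_mesh_descriptors()]; parsing the output
#' reproduces the entries exactly.
#'
#' @param entries Entries tibble.
#' @return XML text as a single string.
#' @export
write_mesh_xml <- function(entries) {
  recs <- vapply(seq_len(nrow(entries)), function(i) {
    ui <- sub("^MESH:", "", entries$concept_id[i])
    trees <- entries$tree_numbers[[i]]
    tree_xml <- if (length(trees) == 0) {
      ""
    } else {
      paste0(
        "    <TreeNumberList>\n",
        paste0(
          "      <TreeNumber>", xml_escape(trees), "</TreeNumber>",
          collapse = "\n"
        ),
        "\n    </TreeNumberList>\n"
      )
    }
    terms <- c(entries$preferred_name[i], entries$synonyms[[i]])
    term_xml <- paste0(
      "          <Term><String>", xml_escape(terms), "</String></Term>",
      collapse = "\n"
    )
    paste0(
      "  <DescriptorRecord>\n",
      "    <DescriptorUI>", xml_escape(ui), "</DescriptorUI>\n",
      "    <DescriptorName><String>", xml_escape(entries$preferred_name[i]),
      "</String></DescriptorName>\n",
      tree_xml,
      "    <ConceptList>\n",
      "      <Concept>\n",
      "        <TermList>\n",
      term_xml, "\n",
      "        </TermList>\n",
      "      </Concept>\n",
      "    </ConceptList>\n",
      "  </DescriptorRecord>"
    )
  }, "")
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<DescriptorRecordSet>",
    recs,
    "</DescriptorRecordSet>",
    ""
  ), collapse = "\n")
}

# Filler tokens contain a digit, so no n-gram containing one can match a
# lexicon term (synthetic disease names are alphabetic).
filler_token <- function(n) {
  paste0("w", sample(9999, n, replace = TRUE), "x")
}

#' Generate a synthetic annotated corpus with planted mentions
#'
#' Emulates a query-retrieved abstract corpus: each document plants
#' surface forms of sampled disease concepts (optionally biased to
#' include target diseases) between digit-bearing filler tokens, at
#' recorded character offsets in the composed `title + " " + abstract`
#' text. Planted surfaces are always flanked by filler, so token-boundary
#' recognition against the same vocabulary recovers the gold annotations
#' exactly. Per-pair document-level co-mention counts are recorded as
#' generator ground truth, bookkept directly from the planted concept
#' sets.
#'
#' @param entries Lexicon entries tibble (the generator vocabulary).
#' @param n_docs Number of documents.
#' @param seed Integer seed (required).
#' @param mean_mentions Mean planted mentions per document (Poisson,
#'   shifted to at least `min_mentions`; default 3).
#' @param min_mentions Minimum planted mentions per document (default 0).
#' @param targets Character vector of target concept identifiers
#'   (optional).
#' @param target_inclusion_rate Probability that a document includes
#'   1-3 target diseases among its planted concepts (default 0.5 when
#'   targets are given).
#' @param allow_repeats Allow the same concept to be planted more than
#'   once in a document (default `TRUE`).
#' @return List with `documents`, `gold` (mentions tibble with final
#'   concept identifiers), and `truth`: a list carrying `pair_counts`
#'   (tibble `concept_a`, `concept_b`, `support`) and `doc_concepts`
#'   (list of planted distinct concept sets per document).
#' @export
generate_corpus <- function(entries, n_docs, seed, mean_mentions = 3,
                            min_mentions = 0, targets = NULL,
                            target_inclusion_rate = 0.5,
                            allow_repeats = TRUE) {
  stopifnot(n_docs >= 0)
  surfaces <- setNames(
    purrr::map2(
      entries$preferred_name, entries$synonyms,
      function(p, s) c(p, s)
    ),
    entries$concept_id
  )
  vocab <- entries$concept_id
  non_targets <- setdiff(vocab, targets)
  with_local_seed(seed, {
    docs <- vector("list", n_docs)
    gold <- vector("list", n_docs)
    doc_concepts <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("SYN%06d", d)
      k <- max(min_mentions, rpois(1, mean_mentions))
      planted <- character(0)
      if (!is.null(targets) && length(targets) > 0 && k > 0 &&
        runif(1) < target_inclusion_rate) {
        planted <- sample(targets, min(sample(1:3, 1), length(targets), k))
      }
      remaining <- k - length(planted)
      if (remaining > 0) {
        pool <- if (allow_repeats) {
          sample(non_targets, remaining, replace = TRUE)
        } else {
          sample(
            setdiff(non_targets, planted),
            min(remaining, length(setdiff(non_targets, planted)))
          )
        }
        planted <- c(planted, pool)
      }
      planted <- sample(planted) # shuffle order of appearance
      title <- paste(filler_token(3), collapse = " ")
      # abstract: filler, then alternating (surface, filler) blocks
      pieces <- filler_token(1)
      spans <- list()
      pos <- nchar(title) + 1L + nchar(pieces[1]) # 0-based cursor in composed text
      for (cid in planted) {
        surf <- sample(surfaces[[cid]], 1)
        start <- pos + 1L # the joining space
        spans[[length(spans) + 1]] <- list(
          concept_id = cid, surface = surf,
          start = start, end = start + nchar(surf)
        )
        filler <- filler_token(1)
        pieces <- c(pieces, surf, filler)
        pos <- start + nchar(surf) + 1L + nchar(filler)
      }
      abstract <- paste(pieces, collapse = " ")
      docs[[d]] <- tibble(doc_id = doc_id, title = title, abstract = abstract)
      doc_concepts[[d]] <- sort(unique(planted))
      gold[[d]] <- if (length(spans) == 0) {
        new_mentions()
      } else {
        new_mentions(
          doc_id = doc_id,
          start = vapply(spans, `[[`, 0L, "start"),
          end = vapply(spans, `[[`, 0L, "end"),
          surface = vapply(spans, `[[`, "", "surface"),
          entity_type = "Disease",
          concept_id = vapply(spans, `[[`, "", "concept_id"),
          raw_concept = vapply(spans, `[[`, "", "concept_id")
        )
      }
    }
    documents <- if (n_docs == 0) {
      new_documents(character(), character(), character())
    } else {
      bind_rows(docs)
    }
    gold <- sort_mentions(bind_rows(c(list(new_mentions()), gold)))
    names(doc_concepts) <- documents$doc_id
    validate_corpus(documents, gold)
    list(
      documents = documents,
      gold = gold,
      truth = list(
        pair_counts = truth_pair_counts(doc_concepts),
        doc_concepts = doc_concepts
      )
    )
  })
}

# Generator-side co-mention bookkeeping from planted concept sets.
truth_pair_counts <- function(doc_concepts) {
  counts <- new.env(parent = emptyenv())
  for (cc in doc_concepts) {
    if (length(cc) < 2) next
    for (i in seq_len(length(cc) - 1)) {
      for (j in seq(i + 1, length(cc))) {
        key <- paste(cc[i], cc[j], sep = "\r")
        prev <- if (exists(key, envir = counts, inherits = FALSE)) {
          get(key, envir = counts)
        } else {
          0L
        }
        assign(key, prev + 1L, envir = counts)
      }
    }
  }
  keys <- sort(ls(counts))
  if (length(keys) == 0) {
    return(tibble(
      concept_a = character(), concept_b = character(), support = integer()
    ))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  tibble(
    concept_a = parts[, 1], concept_b = parts[, 2],
    support = vapply(keys, function(k) counts[[k]], 0L, USE.NAMES = FALSE)
  )
}

#' Corrupt gold annotations with controlled error rates
#'
#' Produces a degraded prediction set with analytically known expected
#' scores, for calibrating the evaluation module: each gold mention is
#' dropped with probability `fn_rate`; each surviving mention has its
#' boundaries jittered with probability `boundary_jitter_rate` (one
#' character, staying in bounds) and its concept identifier swapped for a
#' different one with probability `misnormalization_rate`; for each gold
#' mention a spurious mention over a free filler token is inserted with
#' probability `fp_rate`. With jitter and misnormalization at 0, the
#' expected span-level recall is `1 - fn_rate` and the expected precision
#' is `(1 - fn_rate) / (1 - fn_rate + fp_rate)`.
#'
#' @param documents Documents tibble.
#' @param gold Gold mentions tibble.
#' @param seed Integer seed (required).
#' @param fp_rate,fn_rate,boundary_jitter_rate,misnormalization_rate
#'   Proportions in `[0, 1]` (defaults 0).
#' @param concept_pool Identifiers to draw spurious/misnormalized
#'   concepts from (default: those present in `gold`).
#' @return Predicted mentions tibble.
#' @export
corrupt_annotations <- function(documents, gold, seed, fp_rate = 0,
                                fn_rate = 0, boundary_jitter_rate = 0,
                                misnormalization_rate = 0,
                                concept_pool = NULL) {
  stopifnot(all(c(fp_rate, fn_rate, boundary_jitter_rate,
    misnormalization_rate) >= 0))
  if (is.null(concept_pool)) concept_pool <- unique(gold$concept_id)
  texts <- composed_texts(documents)
  with_local_seed(seed, {
    keep <- runif(nrow(gold)) >= fn_rate
    pred <- gold[keep, , drop = FALSE]
    if (nrow(pred) > 0 && boundary_jitter_rate > 0) {
      jit <- runif(nrow(pred)) < boundary_jitter_rate
      for (i in which(jit)) {
        len <- nchar(texts[[pred$doc_id[i]]])
        if (pred$start[i] > 0) {
          pred$start[i] <- pred$start[i] - 1L
        } else if (pred$end[i] < len) {
          pred$end[i] <- pred$end[i] + 1L
        }
        pred$surface[i] <- slice_text(
          texts[[pred$doc_id[i]]], pred$start[i], pred$end[i]
        )
      }
    }
    if (nrow(pred) > 0 && misnormalization_rate > 0 &&
      length(concept_pool) > 1) {
      mis <- runif(nrow(pred)) < misnormalization_rate
      for (i in which(mis)) {
        pred$concept_id[i] <- sample(
          setdiff(concept_pool, pred$concept_id[i]), 1
        )
      }
    }
    spurious <- list()
    if (fp_rate > 0 && nrow(gold) > 0) {
      n_ins_per_doc <- table(gold$doc_id[runif(nrow(gold)) < fp_rate])
      for (doc in names(n_ins_per_doc)) {
        text <- texts[[doc]]
        toks <- tokenize(text)
        taken <- pred[pred$doc_id == doc, , drop = FALSE]
        free <- vapply(seq_len(nrow(toks)), function(t) {
          !any(toks$start[t] < taken$end & toks$end[t] > taken$start)
        }, TRUE)
        free_idx <- which(free)
        n_ins <- min(n_ins_per_doc[[doc]], length(free_idx))
        if (n_ins == 0) next
        sel <- sample(free_idx, n_ins)
        spurious[[length(spurious) + 1]] <- new_mentions(
          doc_id = doc,
          start = toks$start[sel], end = toks$end[sel],
          surface = toks$token[sel],
          entity_type = "Disease",
          concept_id = sample(concept_pool, n_ins, replace = TRUE),
          raw_concept = NA_character_
        )
      }
    }
    out <- sort_mentions(bind_rows(c(list(pred), spurious)))
    validate_corpus(documents, out)
    out
  })
}

#' Generate disease gene sets realizing exact pairwise overlaps
#'
#' Constructs gene-association sets whose pairwise intersections equal a
#' requested specification exactly: each requested pair gets a private
#' block of shared genes of the requested size, and each disease is
#' padded with private genes, so no gene belongs to more than two
#' diseases and every intersection is exactly as specified.
#'
#' @param overlaps Tibble with columns `concept_a`, `concept_b`,
#'   `n_shared` (requested intersection sizes; unordered pairs, no
#'   duplicates).
#' @param set_sizes Optional named integer vector of total set sizes per
#'   concept; must be at least the sum of that concept's shared blocks.
#'   Defaults to that sum plus `min_private`.
#' @param min_private Default private padding per disease (default 10).
#' @param seed Integer seed (required; used to shuffle row order).
#' @return Tibble (`concept_id`, `gene_symbol`) in long format.
#' @export
generate_gene_sets <- function(overlaps, set_sizes = NULL, min_private = 10,
                               seed = 1) {
  pc <- canonical_pair(overlaps$concept_a, overlaps$concept_b)
  overlaps <- mutate(overlaps, concept_a = pc$a, concept_b = pc$b)
  if (anyDuplicated(paste(overlaps$concept_a, overlaps$concept_b))) {
    abort_ddaminer("duplicate pair in overlap specification",
      "ddaminer_domain_error"
    )
  }
  diseases <- sort(unique(c(overlaps$concept_a, overlaps$concept_b)))
  shared_total <- setNames(integer(length(diseases)), diseases)
  for (i in seq_len(nrow(overlaps))) {
    shared_total[overlaps$concept_a[i]] <-
      shared_total[overlaps$concept_a[i]] + overlaps$n_shared[i]
    shared_total[overlaps$concept_b[i]] <-
      shared_total[overlaps$concept_b[i]] + overlaps$n_shared[i]
  }
  if (is.null(set_sizes)) {
    set_sizes <- shared_total + min_private
  } else {
    set_sizes <- set_sizes[diseases]
    if (anyNA(set_sizes)) {
      abort_ddaminer("set_sizes must cover every disease in overlaps",
        "ddaminer_domain_error"
      )
    }
    if (any(set_sizes < shared_total)) {
      bad <- diseases[which(set_sizes < shared_total)[1]]
      abort_ddaminer(
        paste0(
          "infeasible overlap specification: shared blocks for ", bad,
          " exceed its set size"
        ),
        "ddaminer_domain_error"
      )
    }
  }
  rows <- list()
  for (i in seq_len(nrow(overlaps))) {
    if (overlaps$n_shared[i] == 0) next
    genes <- sprintf("GS%03d_%04d", i, seq_len(overlaps$n_shared[i]))
    rows[[length(rows) + 1]] <- tibble(
      concept_id = rep(c(overlaps$concept_a[i], overlaps$concept_b[i]),
        each = length(genes)
      ),
      gene_symbol = rep(genes, 2)
    )
  }
  for (j in seq_along(diseases)) {
    n_priv <- set_sizes[[diseases[j]]] - shared_total[[diseases[j]]]
    if (n_priv > 0) {
      rows[[length(rows) + 1]] <- tibble(
        concept_id = diseases[j],
        gene_symbol = sprintf("GP%03d_%04d", j, seq_len(n_priv))
      )
    }
  }
  out <- bind_rows(rows)
  with_local_seed(seed, out[sample(nrow(out)), , drop = FALSE])
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Emits every input kind the toolkit consumes, with a manifest recording
#' the generator ground truth: an abstract table (TSV), gold annotations
#' (PubTator), the lexicon (TSV and MeSH-schema XML), a gene-association
#' table realizing overlaps around the targets, an identifier map, and a
#' manifest JSON with the planted pair counts.
#'
#' @param dir Output directory (created if needed).
#' @param n_docs,n_concepts Corpus and lexicon sizes.
#' @param seed Integer seed (required).
#' @param n_targets Number of target diseases (default 3).
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
write_fixture_bundle <- function(dir, n_docs = 50, n_concepts = 20, seed,
                                 n_targets = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- generate_lexicon(n_concepts, seed = seed)
  targets <- entries$concept_id[seq_len(n_targets)]
  corpus <- generate_corpus(
    entries, n_docs,
    seed = seed + 1, targets = targets
  )
  pairs <- expand_target_pairs(entries$concept_id, targets)
  overlaps <- with_local_seed(seed + 2, mutate(
    pairs,
    n_shared = sample(c(5L, 19L, 20L, 25L, 40L), nrow(pairs), replace = TRUE)
  ))
  genes <- generate_gene_sets(overlaps, seed = seed + 3)
  id_map <- tibble(
    source_id = sprintf("C%07d", seq_along(entries$concept_id)),
    target_id = entries$concept_id
  )
  paths <- list(
    corpus = file.path(dir, "corpus.tsv"),
    gold = file.path(dir, "gold.pubtator"),
    lexicon_tsv = file.path(dir, "lexicon.tsv"),
    lexicon_xml = file.path(dir, "lexicon.xml"),
    genes = file.path(dir, "genes.tsv"),
    id_map = file.path(dir, "id_map.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_abstract_table(corpus$documents, paths$corpus)
  write_pubtator(corpus$documents, corpus$gold, paths$gold)
  write_lexicon_table(entries, paths$lexicon_tsv)
  writeLines(write_mesh_xml(entries), paths$lexicon_xml, sep = "")
  readr::write_tsv(genes, paths$genes, progress = FALSE)
  readr::write_tsv(id_map, paths$id_map, progress = FALSE)
  jsonlite::write_json(
    list(
      seed = seed,
      n_docs = n_docs,
      n_concepts = n_concepts,
      targets = targets,
      pair_counts = corpus$truth$pair_counts,
      gene_overlaps = overlaps
    ),
    paths$manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    entries = entries, corpus = corpus, genes = genes,
    overlaps = overlaps, id_map = id_map, targets = targets, paths = paths
  ))
}

expand_target_pairs <- function(concepts, targets) {
  partners <- setdiff(concepts, targets)
  out <- tidyr::expand_grid(concept_a = targets, concept_b = partners)
  pc <- canonical_pair(out$concept_a, out$concept_b)
  distinct(tibble(concept_a = pc$a, concept_b = pc$b))
}
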