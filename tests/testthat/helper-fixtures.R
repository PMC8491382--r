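# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A hand-written three-concept lexicon used across modules.
tiny_entries <- function() {
  tibble::tibble(
    concept_id = c("MESH:D009101", "MESH:D000740", "MESH:D008223"),
    preferred_name = c("Multiple Myeloma", "Anemia", "Lymphoma"),
    synonyms = list(
      c("myeloma", "plasma cell myeloma"),
      c("anaemia"),
      c("lymphomas")
    ),
    tree_numbers = list("C04.557", "C15.378", "C04.557.386")
  )
}

tiny_lexicon <- function() build_lexicon(tiny_entries())

# Exhaustive one-to-one matching oracle for span-level evaluation:
# enumerates every injective assignment of predictions to gold mentions
# (a prediction may match a gold mention only in the same document with
# the identical span) and returns the maximum number matched.
oracle_max_matching <- function(gold, pred) {
  ng <- nrow(gold)
  np <- nrow(pred)
  if (ng == 0 || np == 0) return(0L)
  compatible <- function(pi, gi) {
    pred$doc_id[pi] == gold$doc_id[gi] &&
      pred$start[pi] == gold$start[gi] &&
      pred$end[pi] == gold$end[gi]
  }
  best <- 0L
  recurse <- function(pi, used, matched) {
    if (pi > np) {
      best <<- max(best, matched)
      return()
    }
    if (matched + (np - pi + 1) <= best) return() # bound
    for (gi in seq_len(ng)) {
      if (!used[gi] && compatible(pi, gi)) {
        used[gi] <- TRUE
        recurse(pi + 1, used, matched + 1L)
        used[gi] <- FALSE
      }
    }
    recurse(pi + 1, used, matched)
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}

# Random tiny corpus of span annotations (no text needed: evaluation only
# looks at doc_id/start/end/concept_id), for oracle-equivalence checks.
random_eval_case <- function() {
  docs <- tibble::tibble(
    doc_id = paste0("d", 1:3),
    title = "title words",
    abstract = paste(rep("x", 50), collapse = " ")
  )
  rand_mentions <- function(n) {
    if (n == 0) return(NULL)
    start <- sample(0:40, n, replace = TRUE)
    tibble::tibble(
      doc_id = sample(docs$doc_id, n, replace = TRUE),
      start = start,
      end = start + sample(1:5, n, replace = TRUE),
      surface = "s",
      entity_type = "Disease",
      concept_id = paste0("MESH:D", sample(3, n, replace = TRUE)),
      raw_concept = NA_character_
    )
  }
  list(
    documents = docs,
    gold = rand_mentions(sample(0:10, 1)),
    pred = rand_mentions(sample(0:10, 1))
  )
}

empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(), start = integer(), end = integer(),
    surface = character(), entity_type = character(),
    concept_id = character(), raw_concept = character()
  )
}
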