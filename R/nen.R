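#' Normalize mention surfaces to concept identifiers
#'
#' Exact lookup of the normalized surface form in the lexicon term index.
#' A surface indexed under several concepts resolves to the
#' lexicographically smallest canonical identifier (a deterministic
#' tie-break; `MESH:` identifiers therefore win over `OMIM:` ones). A
#' surface with no hit maps to the [UNKNOWN] sink rather than being
#' dropped.
#'
#' @param surface Character vector of mention surfaces.
#' @param lexicon A `concept_lexicon`.
#' @return Character vector of canonical concept identifiers (possibly
#'   `UNKNOWN`), same length as `surface`.
#' @examples
#' lex <- build_lexicon(tibble::tibble(
#'   concept_id = "MESH:D009101", preferred_name = "Multiple Myeloma",
#'   synonyms = list(character()), tree_numbers = list("C04.557")
#' ))
#' normalize_mention(c("multiple myeloma", "zzgibberish"), lex)
#' @export
normalize_mention <- function(surface, lexicon) {
  hits <- lookup_term(lexicon, surface)
  vapply(hits, function(ids) {
    if (length(ids) == 0) UNKNOWN else ids[1]
  }, "")
}

#' Fill in concept identifiers on a mentions tibble
#'
#' @param mentions Mentions tibble (typically from [recognize()]).
#' @param lexicon A `concept_lexicon`.
#' @return `mentions` with `concept_id` set by [normalize_mention()].
#' @export
normalize_mentions <- function(mentions, lexicon) {
  mutate(mentions, concept_id = normalize_mention(.data$surface, lexicon))
}

#' Annotate a corpus: recognition followed by normalization
#'
#' Runs the full two-step annotation pipeline over raw documents: the
#' recognizer proposes disease mention spans, then each surface is
#' normalized to a concept identifier (or the [UNKNOWN] sink). Documents
#' failing validation are skipped with a warning and counted in the
#' summary rather than aborting the corpus.
#'
#' @param documents Documents tibble.
#' @param lexicon A `concept_lexicon`.
#' @param max_ngram Longest recognizer window in tokens (default 10).
#' @param recognizer Recognizer engine: a
#'   `function(documents, lexicon, max_ngram)` returning a mentions
#'   tibble. Defaults to the built-in dictionary tagger [recognize()].
#' @return List with `documents` (the documents processed), `mentions`
#'   (annotated mentions with final `concept_id`), and `summary`, a
#'   one-row tibble (`n_documents`, `n_skipped`, `n_mentions`,
#'   `n_unknown`, `unknown_rate`).
#' @export
annotate_corpus <- function(documents, lexicon, max_ngram = 10L,
                            recognizer = recognize) {
  keep <- vapply(seq_len(nrow(documents)), function(i) {
    ok <- tryCatch(
      {
        validate_corpus(documents[i, , drop = FALSE])
        TRUE
      },
      ddaminer_error = function(e) {
        warning(
          "skipping document ", documents$doc_id[i] %||% i, ": ",
          conditionMessage(e),
          call. = FALSE
        )
        FALSE
      }
    )
    ok
  }, TRUE)
  docs <- documents[keep, , drop = FALSE]
  mentions <- if (nrow(docs) == 0) {
    new_mentions()
  } else {
    recognizer(docs, lexicon, max_ngram)
  }
  mentions <- validate_recognizer_output(docs, mentions)
  mentions <- normalize_mentions(mentions, lexicon)
  summary <- tibble(
    n_documents = nrow(docs),
    n_skipped = sum(!keep),
    n_mentions = nrow(mentions),
    n_unknown = sum(is_unknown(mentions$concept_id)),
    unknown_rate = ifelse(
      nrow(mentions) == 0, 0,
      sum(is_unknown(mentions$concept_id)) / nrow(mentions)
    )
  )
  list(documents = docs, mentions = mentions, summary = summary)
}
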