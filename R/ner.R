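#' Tokenize text into character-offset spans
#'
#' Tokens are maximal runs of letters or digits; everything else is a
#' separator. Offsets are 0-based, half-open, into the supplied text.
#'
#' @param text A single string.
#' @return Tibble with columns `start`, `end`, `token`, one row per
#'   token, in text order.
#' @examples
#' tokenize("B-cell lymphoma.")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  loc <- stringr::str_locate_all(text, "[\\p{L}\\p{N}]+")[[1]]
  if (nrow(loc) == 0) {
    return(tibble(start = integer(), end = integer(), token = character()))
  }
  tibble(
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2]),
    token = substring(text, loc[, 1], loc[, 2])
  )
}

#' Recognize disease mentions with a dictionary longest-match tagger
#'
#' The built-in recognizer engine: a greedy left-to-right scan over token
#' n-grams of the composed text (`title + " " + abstract`). At each token
#' position the longest window (up to `max_ngram` tokens, capped by the
#' longest term in the lexicon) whose normalized form hits the lexicon
#' term index is emitted as a mention and the scan resumes after it, so
#' output mentions never overlap and are anchored to token boundaries
#' (no partial-word hits). Deterministic: identical input and
#' configuration give identical output.
#'
#' Any component mapping documents to a valid mentions tibble can replace
#' this engine in the pipeline; [validate_recognizer_output()] checks the
#' contract.
#'
#' @param documents Documents tibble (`doc_id`, `title`, `abstract`).
#' @param lexicon A `concept_lexicon` from [build_lexicon()].
#' @param max_ngram Longest candidate window in tokens (default 10).
#' @return Mentions tibble with `entity_type = "Disease"` and
#'   `concept_id = NA` (normalization is a separate step, see
#'   [normalize_mentions()]).
#' @export
recognize <- function(documents, lexicon, max_ngram = 10L) {
  stopifnot(inherits(lexicon, "concept_lexicon"), max_ngram >= 1)
  if (length(ls(lexicon$term_index)) == 0) {
    abort_ddaminer("lexicon is empty", "ddaminer_validation_error")
  }
  cap <- min(as.integer(max_ngram), max(1L, lexicon$max_term_tokens))
  index <- lexicon$term_index
  texts <- composed_texts(documents)
  per_doc <- purrr::map2(documents$doc_id, texts, function(id, text) {
    toks <- tokenize(text)
    nt <- nrow(toks)
    starts <- integer()
    ends <- integer()
    i <- 1L
    while (i <= nt) {
      hit_n <- 0L
      for (n in seq(min(cap, nt - i + 1L), 1L)) {
        cand <- slice_text(text, toks$start[i], toks$end[i + n - 1L])
        key <- normalize_term(cand)
        if (key != "" && exists(key, envir = index, inherits = FALSE)) {
          hit_n <- n
          break
        }
      }
      if (hit_n > 0L) {
        starts <- c(starts, toks$start[i])
        ends <- c(ends, toks$end[i + hit_n - 1L])
        i <- i + hit_n
      } else {
        i <- i + 1L
      }
    }
    if (length(starts) == 0) return(new_mentions())
    new_mentions(
      doc_id = rep(id, length(starts)),
      start = starts, end = ends,
      surface = slice_text(text, starts, ends),
      entity_type = "Disease",
      concept_id = NA_character_,
      raw_concept = NA_character_
    )
  })
  sort_mentions(bind_rows(c(list(new_mentions()), per_doc)))
}

#' Validate recognizer-contract conformance
#'
#' Checks that a mentions tibble satisfies the recognizer plug-in
#' contract against its documents: valid sorted non-overlapping spans
#' within each document, surfaces matching the composed-text slice, and
#' nonempty entity types.
#'
#' @param documents Documents tibble.
#' @param mentions Candidate mentions tibble.
#' @return `mentions` (sorted), invisibly; errors on violation.
#' @export
validate_recognizer_output <- function(documents, mentions) {
  validate_corpus(documents, mentions)
  if (nrow(mentions) > 0 &&
    any(is.na(mentions$entity_type) | mentions$entity_type == "")) {
    abort_ddaminer("mention entity_type must be nonempty",
      "ddaminer_validation_error"
    )
  }
  mentions <- sort_mentions(mentions)
  overlap <- mentions %>%
    group_by(.data$doc_id) %>%
    summarise(
      bad = any(.data$start < dplyr::lag(.data$end, default = -1L)),
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    abort_ddaminer(
      paste0(
        "overlapping mentions in document ",
        overlap$doc_id[which(overlap$bad)[1]]
      ),
      "ddaminer_validation_error"
    )
  }
  invisible(mentions)
}
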