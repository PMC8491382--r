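#' Normalize a term for lexicon lookup
#'
#' The deterministic key under which lexicon synonyms are indexed and
#' mention surfaces are looked up: Unicode compatibility normalization
#' with case folding (NFKC casefold), every punctuation run replaced by a
#' single space (so `"graft-versus-host"` keeps its token boundaries),
#' whitespace collapsed, and leading/trailing space stripped. Idempotent.
#'
#' @param x Character vector.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term("Graft-versus-Host Disease")
#' @export
normalize_term <- function(x) {
  x <- stringi::stri_trans_nfkc_casefold(as.character(x))
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}]+", " ")
  stringr::str_squish(x)
}

#' Build a concept lexicon from entries
#'
#' Constructs the lookup structure used by the recognizer and normalizer:
#' a term index mapping every normalized name and synonym to the set of
#' concept identifiers that carry it. Terms shared by several concepts
#' map to the full identifier set; resolution order is decided at lookup
#' time (see [normalize_mention()]).
#'
#' @param entries Tibble with columns `concept_id` (canonical form),
#'   `preferred_name`, and list-columns `synonyms` and `tree_numbers`
#'   (character vectors, possibly empty). [parse_mesh_descriptors()] and
#'   [read_lexicon_table()] produce this shape.
#' @return A `concept_lexicon` object: list with the `entries` tibble,
#'   a `term_index` environment keyed by normalized term, and
#'   `max_term_tokens`, the longest indexed term in tokens.
#' @export
build_lexicon <- function(entries) {
  entries <- as_tibble(entries)
  if (!"synonyms" %in% names(entries)) entries$synonyms <- list(character())
  if (!"tree_numbers" %in% names(entries)) entries$tree_numbers <- list(character())
  entries$concept_id <- canonical_concept(entries$concept_id)
  if (anyDuplicated(entries$concept_id)) {
    dup <- entries$concept_id[duplicated(entries$concept_id)][1]
    abort_ddaminer(
      paste0("duplicate concept_id in lexicon: ", dup),
      "ddaminer_validation_error"
    )
  }
  long <- tibble(
    concept_id = rep(
      entries$concept_id,
      lengths(entries$synonyms) + 1L
    ),
    term = as.character(unlist(
      purrr::map2(
        entries$preferred_name, entries$synonyms,
        function(p, s) c(p, s)
      ),
      use.names = FALSE
    ) %||% character())
  ) %>%
    mutate(term = normalize_term(.data$term)) %>%
    filter(.data$term != "") %>%
    distinct()
  index <- new.env(parent = emptyenv(), size = max(16L, nrow(long)))
  split_ids <- split(long$concept_id, long$term)
  for (term in names(split_ids)) {
    assign(term, sort(split_ids[[term]]), envir = index)
  }
  structure(
    list(
      entries = entries,
      term_index = index,
      max_term_tokens = if (nrow(long) == 0) 0L else
        max(stringr::str_count(long$term, stringr::fixed(" ")) + 1L)
    ),
    class = "concept_lexicon"
  )
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(
    "<concept_lexicon> ", nrow(x$entries), " concepts, ",
    length(ls(x$term_index)), " indexed terms\n",
    sep = ""
  )
  invisible(x)
}

#' Look up normalized terms in a lexicon index
#'
#' @param lexicon A `concept_lexicon`.
#' @param terms Character vector of terms (normalized internally).
#' @return A list (one element per term) of sorted character vectors of
#'   matching canonical concept identifiers; `character(0)` for misses.
#' @export
lookup_term <- function(lexicon, terms) {
  keys <- normalize_term(terms)
  lapply(keys, function(k) {
    if (k != "" && exists(k, envir = lexicon$term_index, inherits = FALSE)) {
      get(k, envir = lexicon$term_index, inherits = FALSE)
    } else {
      character(0)
    }
  })
}

#' Parse MeSH-schema descriptor XML into lexicon entries
#'
#' Reads the descriptor/supplementary-record subset of the MeSH XML
#' schema (`DescriptorRecordSet` with `DescriptorUI`, `DescriptorName`,
#' `TreeNumberList`, `ConceptList/TermList`, or the `SupplementalRecordSet`
#' equivalents). All `Term/String` values are collected as synonyms; tree
#' numbers are collected when present (supplementary records carry none).
#'
#' @param input Path to an XML file or an XML string.
#' @return Entries tibble (`concept_id`, `preferred_name`, `synonyms`,
#'   `tree_numbers`) suitable for [build_lexicon()].
#' @export
parse_mesh_descriptors <- function(input) {
  doc <- tryCatch(
    xml2::read_xml(input),
    error = function(e) {
      abort_ddaminer(
        paste0("malformed XML: ", conditionMessage(e)),
        "ddaminer_parse_error"
      )
    }
  )
  records <- xml2::xml_find_all(
    doc, "//DescriptorRecord | //SupplementalRecord"
  )
  rows <- purrr::imap(records, function(rec, idx) {
    ui <- xml2::xml_text(xml2::xml_find_first(
      rec, "./DescriptorUI | ./SupplementalRecordUI"
    ))
    if (is.na(ui) || ui == "") {
      abort_ddaminer(
        paste0("record ", idx, " has no DescriptorUI/SupplementalRecordUI"),
        "ddaminer_parse_error"
      )
    }
    name <- xml2::xml_text(xml2::xml_find_first(
      rec,
      "./DescriptorName/String | ./SupplementalRecordName/String"
    ))
    terms <- xml2::xml_text(xml2::xml_find_all(
      rec, ".//ConceptList/Concept/TermList/Term/String"
    ))
    trees <- xml2::xml_text(xml2::xml_find_all(
      rec, "./TreeNumberList/TreeNumber"
    ))
    tibble(
      concept_id = canonical_concept(ui),
      preferred_name = if (is.na(name)) terms[1] %||% "" else name,
      synonyms = list(unique(setdiff(terms, name))),
      tree_numbers = list(trees)
    )
  })
  if (length(rows) == 0) {
    return(tibble(
      concept_id = character(), preferred_name = character(),
      synonyms = list(), tree_numbers = list()
    ))
  }
  bind_rows(rows)
}

#' Read lexicon entries from a plain term table
#'
#' A fixture-friendly alternative to MeSH XML: a TSV with columns
#' `concept_id`, `preferred_name`, optional `synonyms` (`|`-separated)
#' and optional `tree_numbers` (`|`-separated).
#'
#' @param input Path or character vector of lines.
#' @return Entries tibble as for [parse_mesh_descriptors()].
#' @export
read_lexicon_table <- function(input) {
  txt <- paste(read_input_lines(input), collapse = "\n")
  tab <- readr::read_tsv(
    I(txt),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("concept_id", "preferred_name")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort_ddaminer(
      paste0("lexicon table missing column(s): ", paste(miss, collapse = ", ")),
      "ddaminer_schema_error"
    )
  }
  split_bar <- function(x) {
    if (is.null(x)) return(rep(list(character()), nrow(tab)))
    lapply(x, function(v) {
      if (is.na(v) || v == "") character() else strsplit(v, "|", fixed = TRUE)[[1]]
    })
  }
  tibble(
    concept_id = canonical_concept(tab$concept_id),
    preferred_name = tab$preferred_name,
    synonyms = split_bar(tab[["synonyms"]]),
    tree_numbers = split_bar(tab[["tree_numbers"]])
  )
}

#' Write lexicon entries as a plain term table
#'
#' @param entries Entries tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lexicon_table <- function(entries, path) {
  out <- entries %>%
    mutate(
      synonyms = vapply(.data$synonyms, paste, "", collapse = "|"),
      tree_numbers = vapply(.data$tree_numbers, paste, "", collapse = "|")
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load a UMLS-CUI-to-concept identifier translation table
#'
#' Two-column TSV `source_id`, `target_id`; a source CUI may repeat to
#' map to several targets (for example a CUI that corresponds to both a
#' MeSH descriptor and an OMIM entry).
#'
#' @param input Path or character vector of lines.
#' @return Tibble (`source_id`, `target_id`) with canonical target
#'   identifiers.
#' @export
load_id_map <- function(input) {
  txt <- paste(read_input_lines(input), collapse = "\n")
  tab <- readr::read_tsv(
    I(txt),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  miss <- setdiff(c("source_id", "target_id"), names(tab))
  if (length(miss) > 0) {
    abort_ddaminer(
      paste0("id map missing column(s): ", paste(miss, collapse = ", ")),
      "ddaminer_schema_error"
    )
  }
  bad <- !grepl("^C[0-9]+$", tab$source_id)
  if (any(bad)) {
    abort_ddaminer(
      paste0("malformed UMLS CUI: ", tab$source_id[which(bad)[1]]),
      "ddaminer_schema_error"
    )
  }
  targets <- canonical_concept(tab$target_id)
  if (any(is_unknown(targets))) {
    abort_ddaminer("id map target_id may not be empty or UNKNOWN",
      "ddaminer_schema_error"
    )
  }
  distinct(tibble(source_id = tab$source_id, target_id = targets))
}

#' Translate identifiers through an ID map
#'
#' Applies a CUI-to-MeSH/OMIM translation table to a set of source
#' identifiers. Cardinality is conserved: every input identifier is
#' accounted for either among the translated sources or in `unmapped`.
#'
#' @param ids Character vector of source identifiers.
#' @param id_map Tibble from [load_id_map()].
#' @param policy `"drop"` (default) leaves unmapped identifiers out of
#'   `translated`; `"keep"` carries them through verbatim as foreign
#'   identifiers (they are still listed in `unmapped`).
#' @return List with `translated` (sorted unique canonical target
#'   identifiers) and `unmapped` (sorted source identifiers with no map
#'   entry).
#' @export
translate_ids <- function(ids, id_map, policy = c("drop", "keep")) {
  policy <- match.arg(policy)
  ids <- unique(as.character(ids))
  hit <- ids %in% id_map$source_id
  translated <- sort(unique(id_map$target_id[id_map$source_id %in% ids[hit]]))
  unmapped <- sort(ids[!hit])
  if (policy == "keep") translated <- sort(unique(c(translated, unmapped)))
  list(translated = translated, unmapped = unmapped)
}
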