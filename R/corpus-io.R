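#' Compose the text a document's mention offsets refer to
#'
#' All character offsets in this package index into the composition
#' `title + " " + abstract` (the PubTator convention); when the abstract
#' is empty the composed text is the title alone. Offsets are 0-based and
#' half-open, so a mention with `start = s`, `end = e` covers the
#' characters `substr(text, s + 1, e)`.
#'
#' @param title,abstract Character vectors (recycled to common length).
#' @return Character vector of composed texts.
#' @examples
#' compose_text("Fever study", "Fever and lymphoma.")
#' @export
compose_text <- function(title, abstract = "") {
  abstract <- abstract %||% ""
  abstract[is.na(abstract)] <- ""
  ifelse(abstract == "", title, paste(title, abstract))
}

# Composed text for each row of a documents tibble, named by doc_id.
composed_texts <- function(documents) {
  setNames(compose_text(documents$title, documents$abstract), documents$doc_id)
}

# 0-based half-open slice of composed text.
slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

new_documents <- function(doc_id, title, abstract) {
  tibble(
    doc_id = as.character(doc_id),
    title = as.character(title),
    abstract = as.character(abstract)
  )
}

new_mentions <- function(doc_id = character(), start = integer(),
                         end = integer(), surface = character(),
                         entity_type = character(), concept_id = character(),
                         raw_concept = character()) {
  tibble(
    doc_id = as.character(doc_id),
    start = as.integer(start),
    end = as.integer(end),
    surface = as.character(surface),
    entity_type = as.character(entity_type),
    concept_id = as.character(concept_id),
    raw_concept = as.character(raw_concept)
  )
}

sort_mentions <- function(mentions) {
  arrange(mentions, .data$doc_id, .data$start, .data$end)
}

#' Validate documents and mention offsets
#'
#' Checks the corpus invariants: non-empty unique `doc_id`s, non-empty
#' titles, mention offsets within the composed text with
#' `0 <= start < end <= nchar(text)`, and every mention surface equal to
#' its composed-text slice.
#'
#' @param documents Tibble with columns `doc_id`, `title`, `abstract`.
#' @param mentions Optional mentions tibble with columns `doc_id`,
#'   `start`, `end`, `surface` (and usually `entity_type`, `concept_id`).
#' @return `documents`, invisibly; errors on violation.
#' @export
validate_corpus <- function(documents, mentions = NULL) {
  if (any(is.na(documents$doc_id) | documents$doc_id == "")) {
    abort_ddaminer("document ids must be nonempty", "ddaminer_validation_error")
  }
  if (anyDuplicated(documents$doc_id)) {
    dup <- documents$doc_id[duplicated(documents$doc_id)][1]
    abort_ddaminer(
      paste0("duplicate doc_id: ", dup),
      "ddaminer_validation_error"
    )
  }
  if (any(is.na(documents$title) | documents$title == "")) {
    abort_ddaminer("document titles must be nonempty", "ddaminer_validation_error")
  }
  if (!is.null(mentions) && nrow(mentions) > 0) {
    missing <- setdiff(mentions$doc_id, documents$doc_id)
    if (length(missing) > 0) {
      abort_ddaminer(
        paste0("mentions reference unknown doc_id: ", missing[1]),
        "ddaminer_validation_error"
      )
    }
    texts <- composed_texts(documents)
    txt <- texts[mentions$doc_id]
    bad <- mentions$start < 0 | mentions$start >= mentions$end |
      mentions$end > nchar(txt)
    if (any(bad)) {
      i <- which(bad)[1]
      abort_ddaminer(
        sprintf(
          "mention offsets [%d, %d) out of bounds in document %s",
          mentions$start[i], mentions$end[i], mentions$doc_id[i]
        ),
        "ddaminer_validation_error"
      )
    }
    got <- slice_text(txt, mentions$start, mentions$end)
    mism <- got != mentions$surface
    if (any(mism)) {
      i <- which(mism)[1]
      abort_ddaminer(
        sprintf(
          "mention surface %s does not match text slice %s at [%d, %d) in document %s",
          dQuote(mentions$surface[i]), dQuote(got[i]),
          mentions$start[i], mentions$end[i], mentions$doc_id[i]
        ),
        "ddaminer_validation_error"
      )
    }
  }
  invisible(documents)
}

#' Read a PubTator-format corpus
#'
#' Parses the plain-text PubTator format used to distribute annotated
#' abstract corpora: blank-line-separated records of `id|t|title` and
#' `id|a|abstract` lines followed by zero or more tab-separated mention
#' lines (`id`, `start`, `end`, `surface`, `type`, `concept`). Composite
#' concept fields (several identifiers joined by `|` or `+`) are reduced
#' to the first identifier, canonicalized with [canonical_concept()];
#' the verbatim field is preserved in the `raw_concept` column.
#'
#' @param input Path to a PubTator file, or a character vector of lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @param validate Check mention offsets against the composed text
#'   (default `TRUE`).
#' @return A list with two tibbles, `documents` (`doc_id`, `title`,
#'   `abstract`) and `mentions` (`doc_id`, `start`, `end`, `surface`,
#'   `entity_type`, `concept_id`, `raw_concept`), mentions sorted by
#'   document, start, end.
#' @seealso [write_pubtator()] for the inverse on canonical-form corpora.
#' @export
read_pubtator <- function(input, validate = TRUE) {
  lines <- read_input_lines(input)
  docs <- list()
  ments <- list()
  cur <- NULL
  flush_doc <- function(cur) {
    if (is.null(cur$title)) {
      abort_ddaminer(
        paste0("record for document ", cur$id %||% "?", " has no title line"),
        "ddaminer_parse_error"
      )
    }
    cur
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") {
      if (!is.null(cur)) {
        docs[[length(docs) + 1]] <- flush_doc(cur)
        cur <- NULL
      }
      next
    }
    tm <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(tm) == 4) {
      if (is.null(cur)) cur <- list(id = tm[2], abstract = "", mentions = list())
      if (tm[3] == "t") cur$title <- tm[4] else cur$abstract <- tm[4]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 5 || is.null(cur)) {
      abort_ddaminer(
        paste0("malformed PubTator line ", i, ": ", dQuote(line)),
        "ddaminer_parse_error"
      )
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end)) {
      abort_ddaminer(
        paste0("non-numeric offsets on line ", i),
        "ddaminer_parse_error"
      )
    }
    raw <- if (length(fields) >= 6) fields[6] else ""
    first_id <- strsplit(raw, "[|+]")[[1]][1] %||% ""
    if (is.na(first_id)) first_id <- ""
    cur$mentions[[length(cur$mentions) + 1]] <- list(
      doc_id = fields[1], start = start, end = end, surface = fields[4],
      entity_type = fields[5], concept_id = canonical_concept(first_id),
      raw_concept = raw
    )
  }
  if (!is.null(cur)) docs[[length(docs) + 1]] <- flush_doc(cur)

  documents <- new_documents(
    doc_id = vapply(docs, `[[`, "", "id"),
    title = vapply(docs, function(d) d$title, ""),
    abstract = vapply(docs, `[[`, "", "abstract")
  )
  mention_rows <- unlist(lapply(docs, `[[`, "mentions"), recursive = FALSE)
  mentions <- if (length(mention_rows) == 0) {
    new_mentions()
  } else {
    sort_mentions(bind_rows(lapply(mention_rows, as_tibble)))
  }
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  if (validate) validate_corpus(documents, mentions)
  list(documents = documents, mentions = mentions)
}

#' Write a corpus in canonical PubTator form
#'
#' Serializes documents and mentions to PubTator text. On corpora already
#' in canonical form (canonical concept rendering in the concept field,
#' mentions sorted), `read_pubtator()` and `write_pubtator()` are exact
#' inverses.
#'
#' @param documents,mentions Tibbles as returned by [read_pubtator()].
#' @param path Optional file path; when supplied the text is also written
#'   there.
#' @return The PubTator text as a single string, invisibly when `path`
#'   is given.
#' @export
write_pubtator <- function(documents, mentions = NULL, path = NULL) {
  if (is.null(mentions)) mentions <- new_mentions()
  validate_corpus(documents, mentions)
  mentions <- sort_mentions(mentions)
  blocks <- vapply(seq_len(nrow(documents)), function(i) {
    id <- documents$doc_id[i]
    m <- mentions[mentions$doc_id == id, , drop = FALSE]
    lines <- c(
      paste0(id, "|t|", documents$title[i]),
      paste0(id, "|a|", documents$abstract[i])
    )
    if (nrow(m) > 0) {
      concept <- ifelse(
        !is.na(m$raw_concept) & m$raw_concept != "",
        m$raw_concept, m$concept_id
      )
      concept[is.na(concept)] <- UNKNOWN
      lines <- c(lines, paste(
        m$doc_id, m$start, m$end, m$surface, m$entity_type, concept,
        sep = "\t"
      ))
    }
    paste0(paste(lines, collapse = "\n"), "\n")
  }, "")
  out <- paste(blocks, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

#' Read a plain abstract table
#'
#' Ingests a delimited table of raw documents with header columns `id`,
#' `title`, `abstract` (for example a table exported from a PubMed query).
#'
#' @param input Path to the file or a character vector of lines.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return A documents tibble (`doc_id`, `title`, `abstract`).
#' @export
read_abstract_table <- function(input, delim = "\t") {
  txt <- paste(read_input_lines(input), collapse = "\n")
  tab <- readr::read_delim(
    I(txt),
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("id", "title", "abstract")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort_ddaminer(
      paste0("abstract table missing column(s): ", paste(miss, collapse = ", ")),
      "ddaminer_schema_error"
    )
  }
  docs <- new_documents(tab$id, tab$title, tidyr::replace_na(tab$abstract, ""))
  validate_corpus(docs)
  docs
}

#' Write an abstract table
#'
#' @param documents Documents tibble.
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_abstract_table <- function(documents, path, delim = "\t") {
  out <- documents %>%
    select(id = "doc_id", "title", "abstract")
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

# Accept a path or in-memory text for the read_* functions.
read_input_lines <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    return(readr::read_lines(input, progress = FALSE))
  }
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}
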