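new_edges <- function(df) {
  structure(as_tibble(df), class = c("dda_edges", class(tibble())))
}

#' Co-mention pairs within single documents
#'
#' A co-mention relates two distinct disease concepts that appear
#' together in the same document (title and/or abstract). Each unordered
#' pair is contributed at most once per document regardless of how many
#' times either concept is mentioned; [UNKNOWN] concepts never
#' participate, and a concept never pairs with itself.
#'
#' @param mentions Annotated mentions tibble (with `concept_id`).
#' @return Tibble (`doc_id`, `concept_a`, `concept_b`) with
#'   `concept_a < concept_b` (canonical pair order), one row per
#'   document-level pair.
#' @export
document_comentions <- function(mentions) {
  ids <- mentions %>%
    filter(!is_unknown(.data$concept_id)) %>%
    distinct(.data$doc_id, .data$concept_id)
  per_doc <- split(ids$concept_id, ids$doc_id)
  rows <- purrr::imap(per_doc, function(cc, d) {
    cc <- sort(cc)
    if (length(cc) < 2) return(NULL)
    pairs <- utils::combn(cc, 2)
    tibble(doc_id = d, concept_a = pairs[1, ], concept_b = pairs[2, ])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      doc_id = character(), concept_a = character(), concept_b = character()
    ))
  }
  arrange(out, .data$doc_id, .data$concept_a, .data$concept_b)
}

#' Aggregate document-level co-mentions into DDA edges
#'
#' One edge per observed unordered concept pair; the edge support is the
#' number of documents in which the pair co-occurs (document granularity,
#' not mention-occurrence granularity), and the contributing documents
#' are kept as provenance. Set `count_mode = "occurrence"` to weight each
#' document by the number of distinct mention-level pairings instead.
#'
#' @param mentions Annotated mentions tibble.
#' @param count_mode `"document"` (default) or `"occurrence"`.
#' @return A `dda_edges` tibble: `concept_a`, `concept_b` (canonical
#'   order), `support`, `source = "comention"`, `n_docs`, and list-column
#'   `doc_ids`.
#' @export
aggregate_comentions <- function(mentions, count_mode = c("document", "occurrence")) {
  count_mode <- match.arg(count_mode)
  pairs <- document_comentions(mentions)
  if (count_mode == "occurrence") {
    occ <- mentions %>%
      filter(!is_unknown(.data$concept_id)) %>%
      count(.data$doc_id, .data$concept_id, name = "n_mention")
    pairs <- pairs %>%
      left_join(occ, by = c("doc_id", "concept_a" = "concept_id")) %>%
      rename(n_a = "n_mention") %>%
      left_join(occ, by = c("doc_id", "concept_b" = "concept_id")) %>%
      rename(n_b = "n_mention") %>%
      mutate(weight = .data$n_a * .data$n_b)
  } else {
    pairs$weight <- 1L
  }
  edges <- pairs %>%
    group_by(.data$concept_a, .data$concept_b) %>%
    summarise(
      support = sum(.data$weight),
      n_docs = dplyr::n_distinct(.data$doc_id),
      doc_ids = list(sort(unique(.data$doc_id))),
      .groups = "drop"
    ) %>%
    mutate(source = "comention") %>%
    select(
      "concept_a", "concept_b", "support", "source", "n_docs", "doc_ids"
    ) %>%
    arrange(.data$concept_a, .data$concept_b)
  new_edges(edges)
}

# Rows of `edges` with exactly one endpoint in `targets`, plus the
# identity of the target and partner endpoints.
split_target_edges <- function(edges, targets) {
  a_in <- edges$concept_a %in% targets
  b_in <- edges$concept_b %in% targets
  single <- xor(a_in, b_in)
  out <- edges[single, , drop = FALSE]
  out$target <- ifelse(a_in[single], out$concept_a, out$concept_b)
  out$partner <- ifelse(a_in[single], out$concept_b, out$concept_a)
  list(
    single = out,
    target_target = edges[a_in & b_in, , drop = FALSE],
    other = edges[!a_in & !b_in, , drop = FALSE]
  )
}

#' Rank target-linked DDA edges and keep the top k
#'
#' Restricts a DDA edge list to edges joining exactly one target disease
#' to a partner disease, keeps only partners linked to at least
#' `min_target_links` distinct targets, ranks by support (descending,
#' ties broken by the canonical pair rendering) and returns the top `k`.
#' Target-target edges are reported separately in the
#' `"target_target"` attribute of the result.
#'
#' With `rank_by = "partners"` the ranking unit is the partner disease
#' (by total support across its target links) and all edges of the top
#' `k` partners are returned.
#'
#' @param edges A `dda_edges` tibble.
#' @param targets Character vector of target concept identifiers.
#' @param k Number of edges (or partners) to keep (default 100).
#' @param min_target_links Minimum number of distinct targets a partner
#'   must be linked to (default 2).
#' @param rank_by `"edges"` (default) or `"partners"`.
#' @return A ranked `dda_edges` tibble with extra columns `target`,
#'   `partner` and `rank`, and attribute `target_target`.
#' @export
rank_and_filter <- function(edges, targets, k = 100L, min_target_links = 2L,
                            rank_by = c("edges", "partners")) {
  rank_by <- match.arg(rank_by)
  if (length(targets) == 0) {
    abort_ddaminer("targets must be nonempty", "ddaminer_domain_error")
  }
  stopifnot(k >= 1)
  parts <- split_target_edges(edges, targets)
  cand <- parts$single
  eligible <- cand %>%
    group_by(.data$partner) %>%
    summarise(
      n_targets = dplyr::n_distinct(.data$target),
      total_support = sum(.data$support),
      .groups = "drop"
    ) %>%
    filter(.data$n_targets >= min_target_links)
  cand <- filter(cand, .data$partner %in% eligible$partner)
  if (rank_by == "partners") {
    top_partners <- eligible %>%
      arrange(dplyr::desc(.data$total_support), .data$partner) %>%
      head(k) %>%
      pull("partner")
    out <- cand %>%
      filter(.data$partner %in% top_partners) %>%
      arrange(dplyr::desc(.data$support), .data$concept_a, .data$concept_b)
  } else {
    out <- cand %>%
      arrange(dplyr::desc(.data$support), .data$concept_a, .data$concept_b) %>%
      head(k)
  }
  out <- mutate(out, rank = row_number())
  out <- new_edges(out)
  attr(out, "target_target") <- new_edges(parts$target_target)
  out
}

#' Partition disease concepts into cancerous and non-cancerous
#'
#' Classification by ontology tree position: a concept is cancerous iff
#' any of its tree numbers in the lexicon starts with one of the given
#' prefixes (default `"C04"`, the Neoplasms branch of the MeSH disease
#' tree). Concepts with no tree numbers in the lexicon are returned as
#' unclassified.
#'
#' @param nodes Character vector of concept identifiers.
#' @param lexicon A `concept_lexicon` carrying tree numbers.
#' @param cancer_prefixes Character vector of tree-number prefixes
#'   (default `"C04"`).
#' @return Tibble (`concept_id`, `class`) with `class` one of
#'   `"cancerous"`, `"non_cancerous"`, `"unclassified"`; exactly one row
#'   per distinct node.
#' @export
partition_by_tree <- function(nodes, lexicon, cancer_prefixes = "C04") {
  nodes <- unique(as.character(nodes))
  trees <- setNames(lexicon$entries$tree_numbers, lexicon$entries$concept_id)
  cls <- vapply(nodes, function(id) {
    tn <- trees[[id]]
    if (is.null(tn) || length(tn) == 0) return("unclassified")
    hit <- any(vapply(
      cancer_prefixes,
      function(p) any(startsWith(tn, p)), TRUE
    ))
    if (hit) "cancerous" else "non_cancerous"
  }, "")
  tibble(concept_id = nodes, class = unname(cls))
}

#' Count distinct non-target partner diseases in an edge list
#'
#' The number of unique diseases an edge list relates to the targets,
#' irrespective of how many target links each has.
#'
#' @param edges A `dda_edges` tibble (or any tibble with `concept_a`,
#'   `concept_b`, or with a precomputed `partner` column).
#' @param targets Character vector of target concept identifiers; not
#'   needed if `edges` carries a `partner` column.
#' @return Integer count of distinct partners.
#' @export
count_unique_partners <- function(edges, targets = NULL) {
  if ("partner" %in% names(edges)) {
    return(dplyr::n_distinct(edges$partner))
  }
  if (is.null(targets)) {
    abort_ddaminer(
      "targets required when edges lack a partner column",
      "ddaminer_domain_error"
    )
  }
  parts <- split_target_edges(edges, targets)
  dplyr::n_distinct(parts$single$partner)
}

#' Export a DDA network as edge-list TSV or GraphML
#'
#' The TSV carries columns `concept_a`, `concept_b`, `support`, `source`,
#' `n_docs`; the GraphML document labels nodes with preferred names when
#' a lexicon is supplied and carries `support`, `source` and `n_docs` as
#' edge attributes. Output is byte-deterministic for a given edge list.
#'
#' @param edges A `dda_edges` tibble.
#' @param format `"tsv"` or `"graphml"`.
#' @param lexicon Optional `concept_lexicon` for node labels.
#' @param path Optional output file.
#' @return The export text, invisibly when `path` is given.
#' @export
export_graph <- function(edges, format = c("tsv", "graphml"),
                         lexicon = NULL, path = NULL) {
  format <- match.arg(format)
  cols <- edges[, intersect(
    c("concept_a", "concept_b", "support", "source", "n_docs"),
    names(edges)
  ), drop = FALSE]
  if (!"n_docs" %in% names(cols)) cols$n_docs <- NA_integer_
  if (!"source" %in% names(cols)) cols$source <- NA_character_
  out <- if (format == "tsv") {
    readr::format_tsv(cols)
  } else {
    graphml_text(cols, lexicon)
  }
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

graphml_text <- function(cols, lexicon) {
  nodes <- sort(unique(c(cols$concept_a, cols$concept_b)))
  labels <- nodes
  if (!is.null(lexicon)) {
    nm <- setNames(lexicon$entries$preferred_name, lexicon$entries$concept_id)
    hit <- nodes %in% names(nm)
    labels[hit] <- nm[nodes[hit]]
  }
  node_xml <- sprintf(
    paste0(
      '    <node id="%s"><data key="name">%s</data>',
      '<data key="label">%s</data></node>'
    ),
    xml_escape(nodes), xml_escape(nodes), xml_escape(labels)
  )
  edge_xml <- sprintf(
    paste0(
      '    <edge source="%s" target="%s">',
      '<data key="support">%s</data>',
      '<data key="src">%s</data>',
      '<data key="n_docs">%s</data></edge>'
    ),
    xml_escape(cols$concept_a), xml_escape(cols$concept_b),
    format(cols$support, scientific = FALSE, trim = TRUE),
    xml_escape(ifelse(is.na(cols$source), "", cols$source)),
    ifelse(is.na(cols$n_docs), "", format(cols$n_docs, trim = TRUE))
  )
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="support" for="edge" attr.name="support" attr.type="double"/>',
    '  <key id="src" for="edge" attr.name="src" attr.type="string"/>',
    '  <key id="n_docs" for="edge" attr.name="n_docs" attr.type="string"/>',
    '  <graph id="ddas" edgedefault="undirected">',
    node_xml,
    edge_xml,
    "  </graph>",
    "</graphml>",
    ""
  ), collapse = "\n")
}

#' Lollipop chart of the strongest DDA edges
#'
#' @param object A `dda_edges` tibble.
#' @param top_n Number of edges to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dda_edges <- function(object, top_n = 20, ...) {
  dat <- object %>%
    arrange(dplyr::desc(.data$support)) %>%
    head(top_n) %>%
    mutate(pair = paste(.data$concept_a, .data$concept_b, sep = " — "))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = stats::reorder(.data$pair, .data$support), y = .data$support)
  ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pair, yend = 0), color = "grey60") +
    ggplot2::geom_point(color = "steelblue", size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "support") +
    ggplot2::theme_minimal()
}
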