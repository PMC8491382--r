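mk_mentions <- function(doc_id, ids) {
  tibble::tibble(
    doc_id = doc_id, start = seq_along(ids), end = seq_along(ids) + 1L,
    surface = "s", entity_type = "Disease", concept_id = ids,
    raw_concept = NA_character_
  )
}

test_that("document co-mentions enumerate distinct unordered pairs", {
  m <- mk_mentions("d1", c("MESH:A", "MESH:B", "MESH:C"))
  pairs <- document_comentions(m)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$concept_a, c("MESH:A", "MESH:A", "MESH:B"))
  expect_equal(pairs$concept_b, c("MESH:B", "MESH:C", "MESH:C"))

  # one concept mentioned five times pairs with nothing
  expect_equal(nrow(document_comentions(
    mk_mentions("d1", rep("MESH:A", 5))
  )), 0)

  # UNKNOWN never pairs
  expect_equal(nrow(document_comentions(
    mk_mentions("d1", c(UNKNOWN, "MESH:A"))
  )), 0)
})

test_that("aggregation counts documents, not mention multiplicity", {
  mentions <- dplyr::bind_rows(
    mk_mentions("d1", c("MESH:A", "MESH:B", "MESH:B")),
    mk_mentions("d2", c("MESH:A", "MESH:B")),
    mk_mentions("d3", c("MESH:A", "MESH:C")),
    mk_mentions("d4", "MESH:A")
  )
  edges <- aggregate_comentions(mentions)
  ab <- edges[edges$concept_a == "MESH:A" & edges$concept_b == "MESH:B", ]
  expect_equal(ab$support, 2L)
  expect_equal(ab$n_docs, 2L)
  expect_equal(ab$doc_ids[[1]], c("d1", "d2"))
  # occurrence mode weights d1 by 1 x 2 mentions
  occ <- aggregate_comentions(mentions, count_mode = "occurrence")
  expect_equal(
    occ$support[occ$concept_a == "MESH:A" & occ$concept_b == "MESH:B"], 3L
  )
  # empty corpus
  expect_equal(nrow(aggregate_comentions(empty_mentions())), 0)
})

test_that("support totals conserve per-document pair counts", {
  entries <- generate_lexicon(10, seed = 77)
  corpus <- generate_corpus(entries, 80, seed = 78, mean_mentions = 4)
  edges <- aggregate_comentions(corpus$gold)
  per_doc <- sum(vapply(
    split(corpus$gold, corpus$gold$doc_id),
    function(m) nrow(document_comentions(m)), 0L
  ))
  expect_equal(sum(edges$support), per_doc)
  # and matches brute-force recount via generator ground truth
  truth <- corpus$truth$pair_counts
  joined <- dplyr::full_join(truth, edges, by = c("concept_a", "concept_b"))
  expect_false(anyNA(joined$support.x))
  expect_false(anyNA(joined$support.y))
  expect_equal(joined$support.x, joined$support.y)
})

test_that("target ranking filters partners and breaks ties canonically", {
  edges <- aggregate_comentions(dplyr::bind_rows(
    mk_mentions("d1", c("T:1", "P:a")), # P:a linked to one target only
    mk_mentions("d2", c("T:1", "P:b")),
    mk_mentions("d3", c("T:2", "P:b")),
    mk_mentions("d4", c("T:2", "P:b")),
    mk_mentions("d5", c("T:1", "P:c")),
    mk_mentions("d6", c("T:2", "P:c")),
    mk_mentions("d7", c("T:1", "T:2")), # target-target, reported separately
    mk_mentions("d8", c("P:a", "P:c")) # no target endpoint
  ))
  ranked <- rank_and_filter(edges, c("T:1", "T:2"), k = 10)
  expect_false("P:a" %in% ranked$partner)
  # hand-computed: P:b-T:2 support 2 first, then ties by canonical pair
  expect_equal(ranked$support, c(2L, 1L, 1L, 1L))
  expect_equal(ranked$concept_a[1], "P:b")
  expect_equal(ranked$target[1], "T:2")
  # tie order: P:b/T:1 < P:c/T:1 < P:c/T:2 canonically
  expect_equal(ranked$concept_a[2:4], c("P:b", "P:c", "P:c"))
  expect_equal(ranked$concept_b[2:4], c("T:1", "T:1", "T:2"))
  tt <- attr(ranked, "target_target")
  expect_equal(nrow(tt), 1)
  expect_equal(tt$concept_a, "T:1")

  # monotone in k: growing k never removes a returned edge
  for (k in 1:4) {
    small <- rank_and_filter(edges, c("T:1", "T:2"), k = k)
    big <- rank_and_filter(edges, c("T:1", "T:2"), k = k + 1)
    expect_equal(
      small[c("concept_a", "concept_b")],
      big[seq_len(nrow(small)), c("concept_a", "concept_b")]
    )
  }

  # min_target_links = 1 admits the singly-linked partner
  loose <- rank_and_filter(edges, c("T:1", "T:2"), k = 10, min_target_links = 1)
  expect_true("P:a" %in% loose$partner)

  expect_error(rank_and_filter(edges, character()),
    class = "ddaminer_domain_error"
  )
})

test_that("partner-ranking mode returns all edges of the top partners", {
  edges <- aggregate_comentions(dplyr::bind_rows(
    mk_mentions("d1", c("T:1", "P:a")),
    mk_mentions("d2", c("T:2", "P:a")),
    mk_mentions("d3", c("T:1", "P:b")),
    mk_mentions("d4", c("T:2", "P:b")),
    mk_mentions("d5", c("T:2", "P:b"))
  ))
  top1 <- rank_and_filter(edges, c("T:1", "T:2"), k = 1, rank_by = "partners")
  expect_setequal(top1$partner, "P:b")
  expect_equal(nrow(top1), 2)
})

test_that("tree-prefix partition classifies cancerous vs non-cancerous", {
  lex <- tiny_lexicon() # D009101: C04.557, D000740: C15.378, D008223: C04.557.386
  part <- partition_by_tree(
    c("MESH:D009101", "MESH:D000740", "MESH:D008223", "MESH:D999999"), lex
  )
  expect_equal(
    part$class,
    c("cancerous", "non_cancerous", "cancerous", "unclassified")
  )
  # three-way partition covers each node exactly once
  expect_equal(nrow(part), 4)
  expect_true(all(table(part$concept_id) == 1))
})

test_that("unique partner counts reproduce the published table bookkeeping", {
  tab <- noncancer_dda_table()
  sm <- tab[tab$system == "comention", ]
  dg <- tab[tab$system == "gene_overlap", ]
  # counting keys on disease names (identifier columns are transposed in
  # some printed rows)
  expect_equal(dplyr::n_distinct(sm$partner_name), 17)
  expect_equal(dplyr::n_distinct(dg$partner_name), 3)
  expect_equal(nrow(sm), 22)
  expect_equal(nrow(dg), 4)
})

test_that("count_unique_partners works from raw edges or partner column", {
  edges <- tibble::tibble(
    concept_a = c("P:a", "P:b", "T:1"),
    concept_b = c("T:1", "T:1", "P:a"),
    support = 1
  )
  expect_equal(count_unique_partners(edges, targets = "T:1"), 2)
  expect_error(count_unique_partners(edges), class = "ddaminer_domain_error")
})

test_that("graph exports are valid and reparse to the same edge multiset", {
  skip_if_not_installed("igraph")
  entries <- generate_lexicon(8, seed = 55)
  corpus <- generate_corpus(entries, 40, seed = 56)
  edges <- aggregate_comentions(corpus$gold)
  tsv <- export_graph(edges, "tsv")
  parsed <- readr::read_tsv(I(tsv), show_col_types = FALSE)
  expect_equal(nrow(parsed), nrow(edges))
  expect_equal(parsed$support, edges$support)

  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(edges, "graphml", lexicon = build_lexicon(entries), path = path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(edges))
  expect_equal(
    igraph::vcount(g),
    dplyr::n_distinct(c(edges$concept_a, edges$concept_b))
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  want <- sort(paste(edges$concept_a, edges$concept_b))
  expect_equal(got, want)
  expect_equal(
    sort(igraph::edge_attr(g, "support")),
    sort(as.double(edges$support))
  )

  # empty graph is still a valid document
  empty <- aggregate_comentions(empty_mentions())
  expect_no_error(xml2::read_xml(export_graph(empty, "graphml")))
  expect_error(export_graph(edges, "gexf"))
})

test_that("repeated exports are byte-identical", {
  entries <- generate_lexicon(6, seed = 60)
  corpus <- generate_corpus(entries, 25, seed = 61)
  lex <- build_lexicon(entries)
  run <- function() {
    ann <- annotate_corpus(corpus$documents, lex)
    edges <- aggregate_comentions(ann$mentions)
    list(
      tsv = export_graph(edges, "tsv"),
      gml = export_graph(edges, "graphml", lexicon = lex)
    )
  }
  expect_identical(run(), run())
})
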