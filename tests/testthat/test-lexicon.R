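test_that("term normalization folds case, punctuation and width, idempotently", {
  expect_equal(normalize_term("Multiple Myeloma"), "multiple myeloma")
  expect_equal(
    normalize_term("graft-versus-host disease"),
    "graft versus host disease"
  )
  expect_equal(normalize_term("  B-cell   lymphoma!! "), "b cell lymphoma")
  set.seed(99)
  random <- vapply(1:200, function(i) {
    paste(sample(c(letters, LETTERS, 0:9, "-", ".", ",", " ", "'", "é"),
      sample(1:30, 1),
      replace = TRUE
    ), collapse = "")
  }, "")
  expect_identical(normalize_term(normalize_term(random)), normalize_term(random))
})

test_that("mesh-schema descriptor XML parses names, synonyms and trees", {
  entries <- generate_lexicon(10, seed = 21)
  parsed <- parse_mesh_descriptors(write_mesh_xml(entries))
  expect_equal(parsed$concept_id, entries$concept_id)
  expect_equal(parsed$preferred_name, entries$preferred_name)
  expect_equal(parsed$synonyms, entries$synonyms)
  expect_equal(parsed$tree_numbers, entries$tree_numbers)
})

test_that("records without tree numbers give empty tree sets", {
  xml <- paste0(
    '<?xml version="1.0"?><DescriptorRecordSet><DescriptorRecord>',
    "<DescriptorUI>D000001</DescriptorUI>",
    "<DescriptorName><String>Thing</String></DescriptorName>",
    "<ConceptList><Concept><TermList>",
    "<Term><String>Thing</String></Term>",
    "<Term><String>Thing two</String></Term>",
    "<Term><String>Thing three</String></Term>",
    "</TermList></Concept></ConceptList>",
    "</DescriptorRecord></DescriptorRecordSet>"
  )
  parsed <- parse_mesh_descriptors(xml)
  expect_equal(parsed$tree_numbers[[1]], character(0))
  expect_setequal(parsed$synonyms[[1]], c("Thing two", "Thing three"))
})

test_that("records missing a UI and malformed XML are rejected", {
  xml <- paste0(
    "<DescriptorRecordSet><DescriptorRecord>",
    "<DescriptorName><String>NoUI</String></DescriptorName>",
    "</DescriptorRecord></DescriptorRecordSet>"
  )
  expect_error(parse_mesh_descriptors(xml), "record 1",
    class = "ddaminer_parse_error"
  )
  expect_error(parse_mesh_descriptors("<unclosed"),
    class = "ddaminer_parse_error"
  )
})

test_that("lexicon lookup is total over its own synonym set", {
  entries <- generate_lexicon(15, seed = 5)
  lex <- build_lexicon(entries)
  for (i in seq_len(nrow(entries))) {
    for (term in c(entries$preferred_name[i], entries$synonyms[[i]])) {
      hits <- lookup_term(lex, term)[[1]]
      expect_true(entries$concept_id[i] %in% hits)
    }
  }
})

test_that("shared synonyms map to multi-concept sets; duplicates rejected", {
  entries <- tibble::tibble(
    concept_id = c("MESH:D1", "MESH:D2"),
    preferred_name = c("alpha disease", "beta disease"),
    synonyms = list("shared name", "Shared NAME"),
    tree_numbers = list(character(), character())
  )
  lex <- build_lexicon(entries)
  expect_equal(lookup_term(lex, "shared name")[[1]], c("MESH:D1", "MESH:D2"))

  dup <- entries
  dup$concept_id <- c("MESH:D1", "MESH:D1")
  expect_error(build_lexicon(dup), class = "ddaminer_validation_error")

  empty <- build_lexicon(entries[0, ])
  expect_equal(nrow(empty$entries), 0)
})

test_that("lexicon term tables round-trip through TSV", {
  entries <- generate_lexicon(6, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_table(entries, path)
  back <- read_lexicon_table(path)
  expect_equal(back, entries)
})

test_that("id maps translate CUIs with full cardinality accounting", {
  map <- load_id_map(paste(
    "source_id\ttarget_id",
    "C0026764\tMESH:D009101",
    "C0023418\tMESH:D007938",
    "C0023418\tOMIM:601626",
    sep = "\n"
  ))
  res <- translate_ids("C0026764", map)
  expect_equal(res$translated, "MESH:D009101")
  expect_equal(res$unmapped, character(0))

  # one source mapping to two targets yields both
  res2 <- translate_ids("C0023418", map)
  expect_equal(res2$translated, c("MESH:D007938", "OMIM:601626"))

  # empty map leaves everything unmapped
  empty <- map[0, ]
  res3 <- translate_ids(c("C1", "C2"), empty)
  expect_equal(res3$translated, character(0))
  expect_equal(res3$unmapped, c("C1", "C2"))

  # keep policy carries unmapped ids through as foreign
  res4 <- translate_ids(c("C0026764", "C9999999"), map, policy = "keep")
  expect_true(all(c("MESH:D009101", "C9999999") %in% res4$translated))

  # |input| = |translated sources| + |unmapped|
  set.seed(7)
  for (i in 1:20) {
    ids <- paste0("C", sample(1:9, sample(1:6, 1)))
    res <- translate_ids(ids, map)
    n_translated_sources <- sum(unique(ids) %in% map$source_id)
    expect_equal(
      length(unique(ids)),
      n_translated_sources + length(res$unmapped)
    )
  }
})

test_that("id map schema violations are rejected", {
  expect_error(
    load_id_map("source_id\ttarget_id\nnotacui\tMESH:D1"),
    class = "ddaminer_schema_error"
  )
  expect_error(
    load_id_map("source_id\nC1"),
    class = "ddaminer_schema_error"
  )
})
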