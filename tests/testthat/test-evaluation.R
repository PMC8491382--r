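test_that("metric formulas and zero-denominator conventions hold", {
  perfect <- metrics_from_counts(5, 0, 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  zero <- metrics_from_counts(0, 0, 0)
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))

  half <- metrics_from_counts(1, 1, 1)
  expect_equal(c(half$precision, half$recall, half$f1), c(0.5, 0.5, 0.5))

  m <- metrics_from_counts(8, 2, 3)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 11)
  expect_equal(m$f1, 2 * 0.8 * (8 / 11) / (0.8 + 8 / 11))
  # F1 lies between P and R
  expect_gte(m$f1, min(m$precision, m$recall))
  expect_lte(m$f1, max(m$precision, m$recall))

  expect_error(metrics_from_counts(-1, 0, 0), class = "ddaminer_domain_error")
})

test_that("half-up rounding matches published-table conventions", {
  expect_equal(round_half_up(0.885), 0.89)
  expect_equal(round_half_up(0.875), 0.88)
  expect_equal(round_half_up(0.8146, 2), 0.81)
  expect_equal(round_half_up(-0.885), -0.89)
})

test_that("span evaluation counts one-to-one exact matches", {
  docs <- tibble::tibble(doc_id = "d", title = "t", abstract = "a")
  mk <- function(spans) {
    tibble::tibble(
      doc_id = "d", start = vapply(spans, `[[`, 0, 1),
      end = vapply(spans, `[[`, 0, 2), surface = "s",
      entity_type = "Disease", concept_id = "MESH:D1",
      raw_concept = NA_character_
    )
  }
  gold <- mk(list(c(0, 8), c(20, 28)))
  pred <- mk(list(c(0, 8), c(30, 35)))
  res <- evaluate_ner(docs, gold, pred)
  expect_equal(c(res$tp, res$fp, res$fn), c(1L, 1L, 1L))
  expect_equal(c(res$precision, res$recall, res$f1), c(0.5, 0.5, 0.5))

  # identity gives F1 = 1, empty predictions give 0 by convention
  expect_equal(evaluate_ner(docs, gold, gold)$f1, 1)
  none <- evaluate_ner(docs, gold, mk(list()))
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))
})

test_that("mentions outside the corpus raise an alignment error", {
  docs <- tibble::tibble(doc_id = "d", title = "t", abstract = "a")
  stray <- tibble::tibble(
    doc_id = "other", start = 0L, end = 1L, surface = "t",
    entity_type = "Disease", concept_id = "MESH:D1", raw_concept = NA_character_
  )
  expect_error(evaluate_ner(docs, stray, stray),
    class = "ddaminer_alignment_error"
  )
})

test_that("span evaluation equals the exhaustive matching oracle", {
  set.seed(202)
  for (i in 1:120) {
    case <- random_eval_case()
    gold <- case$gold %||% empty_mentions()
    pred <- case$pred %||% empty_mentions()
    res <- evaluate_ner(case$documents, gold, pred)
    tp_oracle <- oracle_max_matching(gold, pred)
    expect_equal(res$tp, tp_oracle)
    expect_equal(res$fp, nrow(pred) - tp_oracle)
    expect_equal(res$fn, nrow(gold) - tp_oracle)
  }
})

test_that("swapping gold and pred swaps precision and recall, F1 invariant", {
  set.seed(303)
  for (i in 1:50) {
    case <- random_eval_case()
    gold <- case$gold %||% empty_mentions()
    pred <- case$pred %||% empty_mentions()
    ab <- evaluate_ner(case$documents, gold, pred)
    ba <- evaluate_ner(case$documents, pred, gold)
    expect_equal(ab$precision, ba$recall)
    expect_equal(ab$recall, ba$precision)
    expect_equal(ab$f1, ba$f1)
    expect_equal(ab$fp, ba$fn)
  }
})

test_that("concept evaluation scores per-document distinct id sets", {
  docs <- tibble::tibble(doc_id = "d", title = "t", abstract = "a")
  mk <- function(ids) {
    tibble::tibble(
      doc_id = "d", start = seq_along(ids), end = seq_along(ids) + 1L,
      surface = "s", entity_type = "Disease", concept_id = ids,
      raw_concept = NA_character_
    )
  }
  gold <- mk(c("MESH:A", "MESH:B"))
  pred <- mk(c("MESH:B", "MESH:C"))
  res <- evaluate_nen(docs, gold, pred, mode = "predicted_spans")
  expect_equal(c(res$tp, res$fp, res$fn), c(1L, 1L, 1L))

  # identical sets, even with duplicate mentions, are perfect
  expect_equal(
    evaluate_nen(docs, gold, mk(c("MESH:A", "MESH:B", "MESH:B")),
      mode = "predicted_spans"
    )$f1, 1
  )

  # UNKNOWN predictions never earn credit
  allunk <- evaluate_nen(docs, gold, mk(c(UNKNOWN, UNKNOWN)),
    mode = "predicted_spans"
  )
  expect_equal(allunk$tp, 0L)
})

test_that("gold-spans mode isolates normalization from recognition", {
  lex <- tiny_lexicon()
  docs <- tibble::tibble(
    doc_id = "d1", title = "Case",
    abstract = "anemia and multiple myeloma"
  )
  gold <- recognize(docs, lex)
  gold$concept_id <- c("MESH:D000740", "MESH:D009101")
  res <- evaluate_nen(docs, gold, mode = "gold_spans", lexicon = lex)
  expect_equal(res$f1, 1)
  expect_error(
    evaluate_nen(docs, gold, mode = "gold_spans"),
    class = "ddaminer_domain_error"
  )
})

test_that("evaluation results expose tidy and glance methods", {
  m <- metrics_from_counts(3, 1, 2)
  td <- tidy(m)
  expect_equal(td$value[td$metric == "precision"], 0.75)
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_false(inherits(gl, "eval_result"))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
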