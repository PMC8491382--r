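#' Precision, recall and F1 from match counts
#'
#' Applies the standard formulas `P = tp / (tp + fp)`,
#' `R = tp / (tp + fn)` and `F1 = 2PR / (P + R)` with the
#' zero-denominator convention that an undefined ratio is 0 (so an empty
#' prediction set has precision 0, an empty gold set has recall 0, and F1
#' is 0 whenever `P + R = 0`).
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return A one-row `eval_result` tibble with columns `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' metrics_from_counts(tp = 5, fp = 0, fn = 0)
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || anyNA(c(tp, fp, fn))) {
    abort_ddaminer("counts must be non-negative", "ddaminer_domain_error")
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  structure(
    tibble(
      tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
      precision = p, recall = r, f1 = f1
    ),
    class = c("eval_result", class(tibble()))
  )
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2PR / (P + R)`, biased toward the smaller of the
#' two; 0 when both are 0. Useful for checking a reported F1 against its
#' reported precision/recall pair.
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @return The F1 score.
#' @examples
#' f1_score(0.87, 0.89)
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
    2 * precision * recall / (precision + recall)
  )
}

#' Round metrics half-up for comparison with published tables
#'
#' Published evaluations usually print two decimals with conventional
#' half-up rounding (0.885 prints as 0.89); base `round()` rounds half to
#' even, so this helper exists for like-for-like comparison.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Align gold and predicted corpora on a shared document set.
check_alignment <- function(documents, gold, pred) {
  for (m in list(gold, pred)) {
    missing <- setdiff(m$doc_id, documents$doc_id)
    if (length(missing) > 0) {
      abort_ddaminer(
        paste0("mentions reference doc_id outside the corpus: ", missing[1]),
        "ddaminer_alignment_error"
      )
    }
  }
  invisible(TRUE)
}

#' Score recognition against gold annotations (exact spans)
#'
#' A predicted mention is a true positive iff an as-yet-unmatched gold
#' mention in the same document has an identical `(start, end)` span;
#' matching is one-to-one. Unmatched predictions count as false
#' positives, unmatched gold mentions as false negatives. No credit is
#' given for partial overlap, the strictest and only fully deterministic
#' span-matching convention.
#'
#' @param documents Documents tibble shared by both annotation sets.
#' @param gold,pred Mentions tibbles.
#' @return An `eval_result` tibble (see [metrics_from_counts()]).
#' @export
evaluate_ner <- function(documents, gold, pred) {
  check_alignment(documents, gold, pred)
  key <- function(m) paste(m$doc_id, m$start, m$end, sep = "\r")
  gk <- table(key(gold))
  pk <- table(key(pred))
  shared <- intersect(names(gk), names(pk))
  tp <- sum(pmin(gk[shared], pk[shared]))
  metrics_from_counts(
    tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp
  )
}

#' Score normalization against gold annotations (concept level)
#'
#' Concept-level scoring over per-document sets of distinct
#' non-[UNKNOWN] concept identifiers: per document,
#' `tp = |gold IDs intersect pred IDs|`, `fp = |pred \ gold|`,
#' `fn = |gold \ pred|`, summed over documents. `UNKNOWN` predictions
#' never earn credit.
#'
#' Two modes mirror the two ways a normalizer is assessed:
#' `"gold_spans"` re-derives predictions by normalizing the gold
#' mentions' own surfaces through the lexicon, isolating normalization
#' quality from recognition errors ("given a perfect NER");
#' `"predicted_spans"` scores the full pipeline output, letting
#' recognition errors cascade into the concept score.
#'
#' @param documents Documents tibble.
#' @param gold Gold mentions tibble (with `concept_id`).
#' @param pred Predicted mentions tibble; ignored in `"gold_spans"` mode.
#' @param mode `"gold_spans"` or `"predicted_spans"`.
#' @param lexicon Required in `"gold_spans"` mode.
#' @return An `eval_result` tibble.
#' @export
evaluate_nen <- function(documents, gold, pred = NULL,
                         mode = c("predicted_spans", "gold_spans"),
                         lexicon = NULL) {
  mode <- match.arg(mode)
  if (mode == "gold_spans") {
    if (is.null(lexicon)) {
      abort_ddaminer("gold_spans mode needs a lexicon", "ddaminer_domain_error")
    }
    pred <- normalize_mentions(gold, lexicon)
  } else if (is.null(pred)) {
    abort_ddaminer("predicted_spans mode needs pred", "ddaminer_domain_error")
  }
  check_alignment(documents, gold, pred)
  id_sets <- function(m) {
    m <- filter(m, !is_unknown(.data$concept_id))
    split(m$concept_id, factor(m$doc_id, levels = documents$doc_id)) |>
      lapply(unique)
  }
  g <- id_sets(gold)
  p <- id_sets(pred)
  tp <- sum(vapply(documents$doc_id, function(d) {
    length(intersect(g[[d]], p[[d]]))
  }, 0L))
  fp <- sum(vapply(documents$doc_id, function(d) {
    length(setdiff(p[[d]], g[[d]]))
  }, 0L))
  fn <- sum(vapply(documents$doc_id, function(d) {
    length(setdiff(g[[d]], p[[d]]))
  }, 0L))
  metrics_from_counts(tp = tp, fp = fp, fn = fn)
}

#' Full evaluation report for an annotated corpus
#'
#' Convenience wrapper computing the three standard scores: span-level
#' recognition, concept-level normalization given perfect recognition
#' (gold spans), and concept-level normalization on the pipeline's own
#' spans (errors cascade).
#'
#' @param documents Documents tibble.
#' @param gold,pred Mentions tibbles.
#' @param lexicon A `concept_lexicon` (for the gold-spans score).
#' @return Named list of `eval_result` tibbles: `ner`, `nen_gold_spans`,
#'   `nen_predicted_spans`.
#' @export
evaluate_pipeline <- function(documents, gold, pred, lexicon) {
  list(
    ner = evaluate_ner(documents, gold, pred),
    nen_gold_spans = evaluate_nen(
      documents, gold,
      mode = "gold_spans", lexicon = lexicon
    ),
    nen_predicted_spans = evaluate_nen(
      documents, gold, pred,
      mode = "predicted_spans"
    )
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation result into metric/value rows
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `value`.
#' @export
tidy.eval_result <- function(x, ...) {
  tibble(
    metric = c("tp", "fp", "fn", "precision", "recall", "f1"),
    value = c(x$tp, x$fp, x$fn, x$precision, x$recall, x$f1)
  )
}

#' One-row summary of an evaluation result
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return The one-row tibble itself, unclassed.
#' @export
glance.eval_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Bar chart of precision, recall and F1
#'
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_result <- function(object, ...) {
  dat <- tidy(object) %>%
    filter(.data$metric %in% c("precision", "recall", "f1")) %>%
    mutate(metric = factor(.data$metric, c("precision", "recall", "f1")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
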