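#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`, the standard set-similarity measure in
#' `[0, 1]`; two empty sets have similarity 0 by convention.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A proportion in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Read a disease-to-gene association table
#'
#' Long-format TSV with columns `concept_id`, `gene_symbol`, one row per
#' association. Gene symbols are compared case-sensitively as given
#' (symbol casing is meaningful); pass `case_fold = TRUE` for dirty
#' inputs.
#'
#' @param input Path or character vector of lines.
#' @param case_fold Upper-case gene symbols on read (default `FALSE`).
#' @return Tibble (`concept_id`, `gene_symbol`), distinct rows, canonical
#'   concept identifiers.
#' @export
read_gene_table <- function(input, case_fold = FALSE) {
  txt <- paste(read_input_lines(input), collapse = "\n")
  tab <- readr::read_tsv(
    I(txt),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  miss <- setdiff(c("concept_id", "gene_symbol"), names(tab))
  if (length(miss) > 0) {
    abort_ddaminer(
      paste0("gene table missing column(s): ", paste(miss, collapse = ", ")),
      "ddaminer_schema_error"
    )
  }
  if (any(is.na(tab$gene_symbol) | tab$gene_symbol == "")) {
    abort_ddaminer("gene symbols must be nonempty", "ddaminer_schema_error")
  }
  sym <- if (case_fold) toupper(tab$gene_symbol) else tab$gene_symbol
  distinct(tibble(
    concept_id = canonical_concept(tab$concept_id),
    gene_symbol = sym
  ))
}

#' Gene-overlap DDA edges from disease gene sets
#'
#' Relates each target disease to every other disease whose gene set
#' shares at least `min_shared` genes with the target's (the inclusive
#' threshold convention: exactly `min_shared` shared genes qualifies).
#' Edge support is the Jaccard index of the two gene sets; the
#' shared-gene count is kept in `n_shared_genes`. Edges are ranked by
#' Jaccard descending, ties broken by the canonical pair rendering.
#'
#' @param gene_table Tibble (`concept_id`, `gene_symbol`) from
#'   [read_gene_table()].
#' @param targets Character vector of target concept identifiers; all
#'   must be present in the table.
#' @param min_shared Minimum shared-gene count (default 20).
#' @return A `dda_edges` tibble: `concept_a`, `concept_b`, `support`
#'   (Jaccard), `source = "gene_overlap"`, `n_shared_genes`, `target`,
#'   `partner`, `rank`.
#' @export
genelist_ddas <- function(gene_table, targets, min_shared = 20L) {
  sets <- split(gene_table$gene_symbol, gene_table$concept_id)
  missing <- setdiff(targets, names(sets))
  if (length(missing) > 0) {
    abort_ddaminer(
      paste0("target absent from gene table: ", missing[1]),
      "ddaminer_domain_error"
    )
  }
  others <- names(sets)
  rows <- purrr::map(targets, function(t) {
    partners <- setdiff(others, t)
    shared <- vapply(
      partners,
      function(p) length(intersect(sets[[t]], sets[[p]])), 0L
    )
    keep <- shared >= min_shared
    if (!any(keep)) return(NULL)
    partners <- partners[keep]
    tibble(
      target = t,
      partner = partners,
      support = vapply(
        partners, function(p) jaccard(sets[[t]], sets[[p]]), 0,
        USE.NAMES = FALSE
      ),
      n_shared_genes = unname(shared[keep])
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(new_edges(tibble(
      concept_a = character(), concept_b = character(), support = double(),
      source = character(), n_shared_genes = integer(),
      target = character(), partner = character(), rank = integer()
    )))
  }
  pc <- canonical_pair(out$target, out$partner)
  out <- out %>%
    mutate(concept_a = pc$a, concept_b = pc$b, source = "gene_overlap") %>%
    # a target pairing with another target appears once per direction
    distinct(.data$concept_a, .data$concept_b, .keep_all = TRUE) %>%
    arrange(dplyr::desc(.data$support), .data$concept_a, .data$concept_b) %>%
    mutate(rank = row_number()) %>%
    select(
      "concept_a", "concept_b", "support", "source", "n_shared_genes",
      "target", "partner", "rank"
    )
  new_edges(out)
}

#' Quantify agreement between two DDA edge lists
#'
#' Matches edges on unordered concept pairs only (support values and
#' sources are ignored) and reports, in the style of a
#' recovered/unique breakdown: the fraction of `b`'s edges also present
#' in `a`, and the fraction of each list that is unique to it. When an
#' `id_map` is supplied, `b`'s endpoints are first translated into `a`'s
#' namespace; edges with an untranslatable endpoint are excluded from
#' the comparison and counted in `n_b_untranslated`.
#'
#' @param a,b Edge tibbles with `concept_a`, `concept_b` columns.
#' @param id_map Optional translation table from [load_id_map()] applied
#'   to `b`.
#' @return A `dda_comparison` object (list) with `n_a`, `n_b`,
#'   `n_b_untranslated`, `recovered_fraction_of_b`, `unique_fraction_of_a`,
#'   `unique_fraction_of_b`, and edge tibbles `shared_edges`, `unique_a`,
#'   `unique_b`.
#' @export
compare_dda_sets <- function(a, b, id_map = NULL) {
  n_b_untranslated <- 0L
  if (!is.null(id_map)) {
    tr <- function(x) {
      hits <- lapply(x, function(id) {
        sort(id_map$target_id[id_map$source_id == id])
      })
      vapply(hits, function(h) if (length(h) == 0) NA_character_ else h[1], "")
    }
    ta <- tr(b$concept_a)
    tb <- tr(b$concept_b)
    ok <- !is.na(ta) & !is.na(tb)
    n_b_untranslated <- sum(!ok)
    b <- b[ok, , drop = FALSE]
    pc <- canonical_pair(ta[ok], tb[ok])
    b$concept_a <- pc$a
    b$concept_b <- pc$b
  }
  pair_key <- function(e) {
    pc <- canonical_pair(e$concept_a, e$concept_b)
    paste(pc$a, pc$b, sep = "\r")
  }
  ka <- unique(pair_key(a))
  kb <- unique(pair_key(b))
  shared <- intersect(ka, kb)
  ua <- setdiff(ka, kb)
  ub <- setdiff(kb, ka)
  n_a <- length(ka)
  n_b <- length(kb)
  if (n_b == 0) {
    warning("second edge set is empty; recovered fraction is vacuously 1",
      call. = FALSE
    )
  }
  key_tbl <- function(keys) {
    if (length(keys) == 0) {
      return(tibble(concept_a = character(), concept_b = character()))
    }
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    arrange(
      tibble(concept_a = parts[, 1], concept_b = parts[, 2]),
      .data$concept_a, .data$concept_b
    )
  }
  structure(
    list(
      n_a = n_a,
      n_b = n_b,
      n_b_untranslated = n_b_untranslated,
      recovered_fraction_of_b = if (n_b == 0) 1 else length(shared) / n_b,
      unique_fraction_of_a = if (n_a == 0) 0 else length(ua) / n_a,
      unique_fraction_of_b = if (n_b == 0) 0 else length(ub) / n_b,
      shared_edges = key_tbl(shared),
      unique_a = key_tbl(ua),
      unique_b = key_tbl(ub)
    ),
    class = "dda_comparison"
  )
}

#' @export
print.dda_comparison <- function(x, ...) {
  cat(
    "<dda_comparison>\n",
    "  edges in a: ", x$n_a, "; edges in b: ", x$n_b,
    " (", x$n_b_untranslated, " untranslatable)\n",
    "  recovered fraction of b: ",
    sprintf("%.3f", x$recovered_fraction_of_b), "\n",
    "  unique fraction of a: ", sprintf("%.3f", x$unique_fraction_of_a),
    "; unique fraction of b: ", sprintf("%.3f", x$unique_fraction_of_b), "\n",
    sep = ""
  )
  invisible(x)
}

#' One-row summary of a DDA network comparison
#'
#' @param x A `dda_comparison`.
#' @param ... Unused.
#' @return One-row tibble of counts and fractions.
#' @export
glance.dda_comparison <- function(x, ...) {
  tibble(
    n_a = x$n_a, n_b = x$n_b, n_b_untranslated = x$n_b_untranslated,
    n_shared = nrow(x$shared_edges),
    recovered_fraction_of_b = x$recovered_fraction_of_b,
    unique_fraction_of_a = x$unique_fraction_of_a,
    unique_fraction_of_b = x$unique_fraction_of_b
  )
}

#' Edge-level membership table for a DDA network comparison
#'
#' @param x A `dda_comparison`.
#' @param ... Unused.
#' @return Tibble (`concept_a`, `concept_b`, `membership`) with
#'   membership one of `"shared"`, `"unique_a"`, `"unique_b"`.
#' @export
tidy.dda_comparison <- function(x, ...) {
  bind_rows(
    mutate(x$shared_edges, membership = "shared"),
    mutate(x$unique_a, membership = "unique_a"),
    mutate(x$unique_b, membership = "unique_b")
  )
}
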