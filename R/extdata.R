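#' Published non-cancerous DDA rows for the blood-cancer targets
#'
#' The transcribed table of non-cancerous disease partners reported among
#' the top-100 blood-cancer DDA edges by two systems: a literature
#' co-mention pipeline (`system = "comention"`, support = co-mention
#' count) and a gene-overlap database (`system = "gene_overlap"`,
#' support = Jaccard index). Identifier columns are reproduced exactly as
#' printed in the source table, where several rows have the partner and
#' target identifiers transposed; bookkeeping over this table should
#' therefore key on the disease names.
#'
#' @return Tibble with columns `system`, `partner_id`, `partner_name`,
#'   `target_id`, `target_name`, `support`.
#' @export
noncancer_dda_table <- function() {
  path <- system.file(
    "extdata", "blood_cancer_noncancer_ddas.tsv",
    package = "ddaminer", mustWork = TRUE
  )
  readr::read_tsv(
    path,
    col_types = readr::cols(
      support = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}
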