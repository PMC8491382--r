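pipeline_config_defaults <- function() {
  list(
    lexicon = list(path = NULL, format = "tsv"),
    corpus = list(path = NULL, format = "tsv", delim = "\t"),
    ner = list(engine = "dictionary", max_ngram = 10L, case_sensitive = FALSE),
    ddanet = list(
      targets = character(), top_k = 100L, min_target_links = 2L,
      count_mode = "document", rank_by = "edges",
      cancer_prefixes = "C04"
    ),
    compare = list(min_shared = 20L, id_map = NULL, gene_table = NULL),
    seed = 1L,
    output_dir = "."
  )
}

#' Read and validate a pipeline configuration
#'
#' Configuration is a single YAML or JSON file mirroring the stage
#' structure (`lexicon`, `corpus`, `ner`, `ddanet`, `compare`, `seed`,
#' `output_dir`). Unknown keys are rejected; unsupplied keys take the
#' documented defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list
#'   of overrides.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- pipeline_config_defaults()
  check_keys <- function(user, ref, prefix = "") {
    bad <- setdiff(names(user), names(ref))
    if (length(bad) > 0) {
      abort_ddaminer(
        paste0("unknown config key: ", prefix, bad[1]),
        "ddaminer_config_error"
      )
    }
  }
  check_keys(user, defaults)
  cfg <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      check_keys(user[[k]], defaults[[k]], paste0(k, "."))
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg$ddanet$targets <- canonical_concept(unlist(cfg$ddanet$targets))
  cfg
}

load_lexicon_from_config <- function(cfg) {
  lx <- cfg$lexicon
  if (is.null(lx$path)) {
    abort_ddaminer("config lexicon.path is required", "ddaminer_config_error")
  }
  entries <- if (identical(lx$format, "xml")) {
    parse_mesh_descriptors(lx$path)
  } else {
    read_lexicon_table(lx$path)
  }
  build_lexicon(entries)
}

#' Run the full annotation-to-network pipeline
#'
#' Executes annotate (recognize + normalize), co-mention aggregation,
#' target ranking/filtering, cancer/non-cancer partitioning and graph
#' export, writing every artifact plus a machine-readable run manifest
#' (config hash, seed, stage counts) to the configured output directory.
#' Reruns with the same inputs and config are byte-identical.
#'
#' @param config A config list from [read_pipeline_config()] (or a path,
#'   which is read first).
#' @return Invisibly, a list with the in-memory results (`annotated`,
#'   `edges`, `ranked`, `partition`, `manifest`) and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_ddaminer(
        paste0("pipeline stage ", dQuote(name), " failed: ",
          conditionMessage(e)
        ),
        "ddaminer_pipeline_error"
      )
    })
  }
  lexicon <- stage("lexicon", load_lexicon_from_config(config))
  documents <- stage("corpus", {
    if (is.null(config$corpus$path)) {
      abort_ddaminer("config corpus.path is required", "ddaminer_config_error")
    }
    if (identical(config$corpus$format, "pubtator")) {
      read_pubtator(config$corpus$path)$documents
    } else {
      read_abstract_table(config$corpus$path, delim = config$corpus$delim)
    }
  })
  annotated <- stage("annotate", annotate_corpus(
    documents, lexicon,
    max_ngram = config$ner$max_ngram
  ))
  edges <- stage("ddas", aggregate_comentions(
    annotated$mentions,
    count_mode = config$ddanet$count_mode
  ))
  targets <- config$ddanet$targets
  ranked <- if (length(targets) > 0) {
    stage("ddas", rank_and_filter(
      edges, targets,
      k = config$ddanet$top_k,
      min_target_links = config$ddanet$min_target_links,
      rank_by = config$ddanet$rank_by
    ))
  } else {
    edges
  }
  partition <- stage("partition", partition_by_tree(
    unique(c(ranked$concept_a, ranked$concept_b)), lexicon,
    cancer_prefixes = config$ddanet$cancer_prefixes
  ))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    annotated = file.path(config$output_dir, "annotated.pubtator"),
    edges = file.path(config$output_dir, "edges.tsv"),
    ranked = file.path(config$output_dir, "ranked_edges.tsv"),
    graphml = file.path(config$output_dir, "network.graphml"),
    partition = file.path(config$output_dir, "node_classes.tsv"),
    manifest = file.path(config$output_dir, "manifest.json")
  )
  stage("export", {
    write_pubtator(annotated$documents, annotated$mentions, paths$annotated)
    export_graph(edges, "tsv", path = paths$edges)
    export_graph(ranked, "tsv", path = paths$ranked)
    export_graph(ranked, "graphml", lexicon = lexicon, path = paths$graphml)
    readr::write_tsv(partition, paths$partition, progress = FALSE)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("ddaminer")),
    config = config,
    config_hash = config_hash(config),
    seed = config$seed,
    counts = list(
      documents = annotated$summary$n_documents,
      skipped = annotated$summary$n_skipped,
      mentions = annotated$summary$n_mentions,
      unknown_mentions = annotated$summary$n_unknown,
      edges = nrow(edges),
      ranked_edges = nrow(ranked),
      non_cancerous_nodes = sum(partition$class == "non_cancerous")
    )
  )
  jsonlite::write_json(
    manifest, paths$manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(list(
    annotated = annotated, edges = edges, ranked = ranked,
    partition = partition, manifest = manifest, paths = paths
  ))
}

# md5 of the canonical JSON serialization of the config.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

# Minimal long-flag parser for the CLI: --key value pairs plus a leading
# subcommand; repeated keys collect into vectors.
parse_cli_args <- function(args) {
  if (length(args) == 0) {
    abort_ddaminer("no subcommand given", "ddaminer_usage_error")
  }
  cmd <- args[1]
  args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      abort_ddaminer(
        paste0("unexpected argument: ", args[i]),
        "ddaminer_usage_error"
      )
    }
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      val <- args[i + 1]
      opts[[key]] <- c(opts[[key]], val)
      i <- i + 2
    }
  }
  list(cmd = cmd, opts = opts)
}

#' Command-line dispatcher
#'
#' Backs the `ddaminer` command-line script (see `inst/cli/ddaminer.R`).
#' Subcommands: `annotate` (PubTator out of raw documents), `evaluate`
#' (JSON scores from gold and predicted PubTator files), `ddas`
#' (co-mention network from annotated PubTator), `compare` (gene-overlap
#' DDAs vs a co-mention edge list), `synth` (fixture bundle), `run`
#' (full pipeline from a config file).
#'
#' Exit status: 0 on success, 2 on usage/config errors, 3 on
#' data/validation errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code.
#' @export
dda_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage_classes <- c("ddaminer_usage_error", "ddaminer_config_error")
  tryCatch(
    {
      parsed <- parse_cli_args(args)
      do_cli(parsed$cmd, parsed$opts)
      0L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      if (inherits(e, usage_classes)) 2L else 3L
    }
  )
}

req_opt <- function(opts, key) {
  if (is.null(opts[[key]])) {
    abort_ddaminer(paste0("missing required option --", key),
      "ddaminer_usage_error"
    )
  }
  opts[[key]]
}

do_cli <- function(cmd, opts) {
  switch(cmd,
    run = {
      run_pipeline(req_opt(opts, "config"))
    },
    annotate = {
      lexicon <- build_lexicon(read_lexicon_table(req_opt(opts, "lexicon")))
      docs <- read_abstract_table(req_opt(opts, "corpus"))
      ann <- annotate_corpus(docs, lexicon)
      write_pubtator(ann$documents, ann$mentions, req_opt(opts, "out"))
    },
    evaluate = {
      gold <- read_pubtator(req_opt(opts, "gold"))
      pred <- read_pubtator(req_opt(opts, "pred"))
      lexicon <- if (!is.null(opts$lexicon)) {
        build_lexicon(read_lexicon_table(opts$lexicon))
      }
      rep <- if (is.null(lexicon)) {
        list(
          ner = evaluate_ner(gold$documents, gold$mentions, pred$mentions),
          nen_predicted_spans = evaluate_nen(
            gold$documents, gold$mentions, pred$mentions,
            mode = "predicted_spans"
          )
        )
      } else {
        evaluate_pipeline(
          gold$documents, gold$mentions, pred$mentions, lexicon
        )
      }
      jsonlite::write_json(
        lapply(rep, function(r) as.list(glance(r))),
        req_opt(opts, "out"),
        auto_unbox = TRUE, digits = NA
      )
    },
    ddas = {
      ann <- read_pubtator(req_opt(opts, "annotated"))
      edges <- aggregate_comentions(
        ann$mentions,
        count_mode = opts[["count-mode"]] %||% "document"
      )
      targets <- opts$targets
      if (!is.null(targets)) {
        edges <- rank_and_filter(
          edges, canonical_concept(targets),
          k = as.integer(opts[["top-k"]] %||% 100L),
          min_target_links = as.integer(opts[["min-target-links"]] %||% 2L)
        )
      }
      export_graph(edges, opts$format %||% "tsv", path = req_opt(opts, "out"))
    },
    compare = {
      genes <- read_gene_table(req_opt(opts, "genes"))
      gene_edges <- genelist_ddas(
        genes, canonical_concept(req_opt(opts, "targets")),
        min_shared = as.integer(opts[["min-shared"]] %||% 20L)
      )
      other <- readr::read_tsv(
        req_opt(opts, "edges"),
        col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE
      )
      id_map <- if (!is.null(opts[["id-map"]])) load_id_map(opts[["id-map"]])
      cmp <- compare_dda_sets(gene_edges, other, id_map = id_map)
      jsonlite::write_json(
        as.list(glance(cmp)), req_opt(opts, "out"),
        auto_unbox = TRUE, digits = NA
      )
    },
    synth = {
      write_fixture_bundle(
        req_opt(opts, "out"),
        n_docs = as.integer(opts[["n-docs"]] %||% 50L),
        n_concepts = as.integer(opts[["n-concepts"]] %||% 20L),
        seed = as.integer(req_opt(opts, "seed"))
      )
    },
    abort_ddaminer(paste0("unknown subcommand: ", cmd), "ddaminer_usage_error")
  )
  invisible(NULL)
}
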