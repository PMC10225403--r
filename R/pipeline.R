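# End-to-end orchestration: preprocessing -> graph -> Hishigaki scoring ->
# module extraction -> MCODE sub-modules -> hubs -> enrichment, with every
# stage count recorded in a JSON run report. The whole path is
# deterministic given its inputs: no stage draws random numbers.

#' Pipeline run configuration
#'
#' Defaults follow the package's reference analysis settings: score cutoff
#' 400 (strict), k = 75 candidates with a 20/50/75/100 retention grid,
#' radius-1 Hishigaki scoring, MCODE at degree cutoff 2 / node score cutoff
#' 0.6 / k-core 2 / max depth 100, top-10% intramodular hubs, intermodular
#' span 3, enrichment alpha 0.05.
#'
#' @param links Path to the STRING-style links file.
#' @param seeds Path to the seed list.
#' @param out_dir Output directory.
#' @param aliases Optional path to a two-column alias TSV.
#' @param annotations Optional path to an annotation file (GMT when the
#'   extension is `.gmt`, two-column TSV otherwise).
#' @param score_cutoff Combined-score cutoff (default 400).
#' @param score_min_inclusive Keep edges scoring exactly `score_cutoff`
#'   (default `FALSE`, i.e. strict `>`).
#' @param k Candidate-list size for the analysis module (default 75).
#' @param k_grid Candidate-list sizes for the seed-retention report.
#' @param radius Hishigaki neighborhood radius (default 1).
#' @param allow_depletion Score seed-depleted neighborhoods too (default
#'   `FALSE`).
#' @param mcode An [mcode_params()] list.
#' @param attach_satellites Satellite-attachment pass after MCODE (default
#'   `FALSE`).
#' @param hub_fraction Intramodular hub fraction (default 0.10).
#' @param min_span Intermodular hub span threshold (default 3).
#' @param alpha Enrichment significance level (default 0.05).
#' @return A `run_config` list.
#' @export
run_config <- function(links, seeds, out_dir,
                       aliases = NULL, annotations = NULL,
                       score_cutoff = 400L, score_min_inclusive = FALSE,
                       k = 75L, k_grid = c(20L, 50L, 75L, 100L),
                       radius = 1L, allow_depletion = FALSE,
                       mcode = mcode_params(),
                       attach_satellites = FALSE,
                       hub_fraction = 0.10, min_span = 3L, alpha = 0.05) {
  assert_that(k >= 1, "`k` must be >= 1")
  for (p in c(links, seeds, aliases, annotations)) {
    assert_that(file.exists(p), sprintf("input path does not exist: %s", p))
  }
  structure(list(links = links, seeds = seeds, out_dir = out_dir,
                 aliases = aliases, annotations = annotations,
                 score_cutoff = as.integer(score_cutoff),
                 score_min_inclusive = isTRUE(score_min_inclusive),
                 k = as.integer(k), k_grid = as.integer(k_grid),
                 radius = as.integer(radius),
                 allow_depletion = isTRUE(allow_depletion),
                 mcode = mcode,
                 attach_satellites = isTRUE(attach_satellites),
                 hub_fraction = hub_fraction,
                 min_span = as.integer(min_span),
                 alpha = alpha),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `mcode` may be a
#' mapping of [mcode_params()] arguments.
#'
#' @param path Path to the YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mcode)) raw$mcode <- do.call(mcode_params, raw$mcode)
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full phenotype-module pipeline
#'
#' Executes preprocessing, Hishigaki scoring, module extraction, MCODE
#' sub-module detection, hub identification and (when annotations are
#' supplied) over-representation analysis, writing tabular/SIF/GraphML
#' outputs and a JSON run report to `config$out_dir`.
#'
#' @param config A [run_config()] (or [read_run_config()]) object.
#' @return Invisibly, a list with `report` (the stage-count summary) and
#'   the main intermediate objects (`network`, `scores`, `module`,
#'   `complexes`, `assignment`, `hubs`, `enrichment`, `retention`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  alias_table <- NULL
  if (!is.null(config$aliases)) {
    alias_table <- stage("aliases", utils::read.table(
      config$aliases, sep = "\t", header = FALSE, colClasses = "character",
      quote = "", comment.char = "#", stringsAsFactors = FALSE))
  }

  edges_raw <- stage("parse", parse_string_links(config$links, alias_table))
  edges_filt <- stage("filter", filter_by_score(
    edges_raw, config$score_cutoff, strict = !config$score_min_inclusive))
  edges <- stage("deduplicate", deduplicate(edges_filt))
  network <- stage("graph", build_graph(edges))
  seeds <- stage("seeds", load_seed_list(config$seeds,
                                         igraph::V(network)$name))

  scores <- stage("prediction", score_all_candidates(
    network, seeds, radius = config$radius,
    overrepresented_only = !config$allow_depletion))
  retention <- stage("retention", seed_retention_report(
    network, seeds, scores, config$k_grid))
  candidates <- stage("selection",
                      suppressWarnings(select_top_k(scores, config$k)))
  module <- stage("module", extract_module(network, seeds, candidates))

  complexes <- stage("mcode", find_complexes(module$graph, config$mcode))
  assignment <- stage("mcode", assign_submodules(
    module, complexes, attach_satellites = config$attach_satellites))
  hubs <- stage("hubs", hub_report(module, assignment,
                                   fraction = config$hub_fraction,
                                   min_span = config$min_span))

  enrichment <- NULL
  if (!is.null(config$annotations)) {
    ann <- stage("enrichment", {
      if (grepl("\\.gmt$", config$annotations, ignore.case = TRUE)) {
        read_gmt(config$annotations)
      } else {
        read_annotation_table(config$annotations)
      }
    })
    enrichment <- stage("enrichment", {
      query <- names(module$roles)[module$roles == "predicted"]
      if (length(query) > 0L) {
        suppressWarnings(enrich(query, ann, igraph::V(network)$name,
                                alpha = config$alpha))
      } else {
        NULL
      }
    })
  }

  prov <- edge_provenance(edges)
  report <- list(
    raw_records = prov$raw_records,
    post_filter_records = prov$score_filter$records_after,
    post_dedup_edges = prov$deduplication$edges_after,
    self_loops_removed = prov$deduplication$self_loops_removed,
    n_nodes = igraph::vcount(network),
    seeds_total = length(seeds$ids),
    seeds_in_network = length(seeds$ids) - length(seeds$missing_from_network),
    seeds_retained = retention$present[match(config$k, retention$k)],
    k = config$k,
    module_size = igraph::vcount(module$graph),
    module_edges = igraph::ecount(module$graph),
    n_submodules = length(complexes),
    submodule_sizes = lengths(lapply(complexes, `[[`, "members")),
    hub_degree_cutoff = hubs$degree_cutoff,
    n_intramodular_hubs = nrow(hubs$intramodular),
    n_intermodular_hubs = nrow(hubs$intermodular),
    n_enriched_terms = if (is.null(enrichment)) NA_integer_
                       else sum(enrichment$significant),
    settings = local({
      s <- unclass(config)[setdiff(names(config),
                                   c("links", "seeds", "aliases",
                                     "annotations", "out_dir"))]
      s$mcode <- unclass(s$mcode)
      s
    })
  )

  stage("write", {
    write_edge_list(edges, file.path(out, "edges.tsv"))
    write_sif(edges, file.path(out, "edges.sif"))
    write_provenance(edges, file.path(out, "provenance.json"))
    write_prediction_table(scores, file.path(out, "candidates.tsv"))
    utils::write.table(retention, file.path(out, "seed_retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(module_node_table(module),
                       file.path(out, "module_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_graphml(module$graph, file.path(out, "module.graphml"))
    utils::write.table(submodule_table(module, assignment),
                       file.path(out, "submodules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_hub_report(hubs, out)
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(out, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(report = report, network = network, scores = scores,
                 retention = retention, module = module,
                 complexes = complexes, assignment = assignment,
                 hubs = hubs, enrichment = enrichment))
}
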