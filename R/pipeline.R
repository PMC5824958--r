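#' Pipeline configuration
#'
#' Collects every input path and stage option for [run_pipeline()]. All
#' referenced paths are checked for existence up front, before any stage
#' runs, so a misconfigured run fails without partial outputs. A YAML file
#' of the same keys can seed the configuration; explicit arguments
#' override file values, which override defaults.
#'
#' @param psm Path to the PSM table (see [read_psm_table()]).
#' @param contaminants Path to a contaminant list; `NULL` uses the
#'   packaged keratin list.
#' @param tissue Path to a tissue catalog TSV.
#' @param gmt Path to a GMT annotation catalog.
#' @param reference Path to the reference gene list (one symbol per line).
#' @param ppi Path to augmentation edges; `NULL` for no augmentation.
#' @param ppi_dialect `"edge_tsv"` or `"mitab25"`.
#' @param id_map Path to a homology mapping TSV; `NULL` to skip mapping.
#' @param bait Bait gene symbol. Default `"ITM2B"`.
#' @param call Calling configuration, a [call_config()].
#' @param tissue_mode `"union"` or `"intersection"` (see [classify_es()]).
#' @param alpha,correction Enrichment options (see [enrich()]).
#' @param out_dir Output directory.
#' @param file Optional YAML file with any of the above keys (flat
#'   key/value document; `call.*` keys map to [call_config()] fields).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(psm = NULL, contaminants = NULL, tissue = NULL,
                            gmt = NULL, reference = NULL, ppi = NULL,
                            ppi_dialect = "edge_tsv", id_map = NULL,
                            bait = "ITM2B", call = call_config(),
                            tissue_mode = "union", alpha = 0.05,
                            correction = "none", out_dir = NULL,
                            file = NULL) {
  cfg <- list(psm = psm, contaminants = contaminants, tissue = tissue,
              gmt = gmt, reference = reference, ppi = ppi,
              ppi_dialect = ppi_dialect, id_map = id_map, bait = bait,
              call = call, tissue_mode = tissue_mode, alpha = alpha,
              correction = correction, out_dir = out_dir)
  supplied <- names(cfg)[c(!missing(psm), !missing(contaminants),
                           !missing(tissue), !missing(gmt),
                           !missing(reference), !missing(ppi),
                           !missing(ppi_dialect), !missing(id_map),
                           !missing(bait), !missing(call),
                           !missing(tissue_mode), !missing(alpha),
                           !missing(correction), !missing(out_dir))]
  if (!is.null(file)) {
    if (!file.exists(file)) stop_format("config file not found: %s", file)
    fromfile <- yaml::read_yaml(file)
    call_keys <- intersect(names(fromfile),
                           c("min_ratio", "mock_aggregation", "min_replicate_support"))
    if (length(call_keys) > 0 && !("call" %in% supplied)) {
      cfg$call <- do.call(call_config, fromfile[call_keys])
    }
    fromfile <- fromfile[setdiff(names(fromfile), call_keys)]
    # precedence: explicit argument > file value > default
    for (key in names(fromfile)) {
      if (key %in% names(cfg) && !(key %in% supplied)) cfg[[key]] <- fromfile[[key]]
    }
  }
  required <- c("psm", "tissue", "gmt", "reference", "out_dir")
  for (key in required) {
    if (is.null(cfg[[key]])) stop_format("pipeline config: '%s' is required", key)
  }
  for (key in c("psm", "contaminants", "tissue", "gmt", "reference",
                "ppi", "id_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_format("pipeline config: %s file does not exist: %s", key, cfg[[key]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full interactome analysis pipeline
#'
#' Executes the stages in order — interactor calling, contaminant
#' filtering, tissue (ES) classification, region Venn partitioning,
#' annotation over-representation, and network construction with topology
#' analysis — writing each stage's output under `out_dir` together with a
#' machine-readable `summary.json` of per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  psm <- read_psm_table(config$psm)
  contaminants <- if (is.null(config$contaminants)) keratin_contaminants()
    else read_contaminants(config$contaminants)
  tissue <- read_tissue_catalog(config$tissue)
  catalog <- read_gmt(config$gmt)
  reference <- readLines(config$reference, warn = FALSE)
  reference <- reference[nzchar(trimws(reference))]
  aug <- if (is.null(config$ppi)) NULL
    else read_interactions(config$ppi, config$ppi_dialect)
  id_map <- if (is.null(config$id_map)) NULL else read_id_mapping(config$id_map)

  calls <- call_interactors(psm, config$call)
  filtered <- filter_contaminants(calls, contaminants)
  n_removed <- attr(filtered, "n_removed")
  write_calls(filtered, out("calls.tsv"))

  es <- classify_es(unique(filtered$gene_symbol), tissue, config$tissue_mode)
  es_symbols <- es_subset(es)
  readr::write_tsv(es[order(es$gene_symbol), c("gene_symbol", "es")],
                   out("es.tsv"), progress = FALSE)

  es_calls <- filtered[toupper(filtered$gene_symbol) %in% es_symbols, ]
  assignment <- calls_to_assignment(es_calls)
  partition <- venn_partition(assignment)
  write_venn_json(partition, out("venn.json"))

  query <- if (is.null(id_map)) es_symbols
    else suppressWarnings(map_identifiers(unique(es_calls$gene_symbol), id_map))
  results <- enrich(query, catalog, reference,
                    alpha = config$alpha, correction = config$correction)
  readr::write_tsv(results, out("enrichment.tsv"), progress = FALSE)

  net_calls <- es_calls
  if (!is.null(id_map)) {
    mapped <- suppressWarnings(map_identifiers(net_calls$gene_symbol, id_map))
    net_calls <- net_calls[net_calls$gene_symbol %in%
                             setdiff(net_calls$gene_symbol,
                                     attr(mapped, "unmapped")), ]
    net_calls$gene_symbol <- unname(id_map[net_calls$gene_symbol])
  }
  graph <- build_network(config$bait, net_calls, aug)
  report <- topology(graph)
  write_graphml(graph, out("network.graphml"))
  write_topology_json(report, out("topology.json"))

  summary <- list(
    n_psm_rows = nrow(psm),
    n_called = length(unique(calls$accession)),
    n_contaminants_removed = n_removed,
    n_after_contaminant_filter = length(unique(filtered$accession)),
    n_es = length(es_symbols),
    venn_cells = as.list(venn_cell_sizes(partition)),
    region_totals = as.list(region_totals(partition)),
    n_terms_tested = nrow(results),
    n_significant_terms = sum(results$significant),
    topology = list(
      n_nodes = report$n_nodes, n_edges = report$n_edges,
      mean_neighbors = report$mean_neighbors,
      mean_clustering = report$mean_clustering,
      expected_random_cc = report$expected_random_cc,
      cc_ratio = report$cc_ratio
    )
  )
  jsonlite::write_json(summary, out("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
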