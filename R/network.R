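#' Map identifiers through a homology table
#'
#' Translates gene symbols through a source -> target map (typically rat
#' symbols to their human homologs). Inputs with no map entry are dropped
#' and reported with a warning, mirroring the losses inherent to homology
#' extrapolation.
#'
#' @param symbols Character vector of identifiers to map.
#' @param map Named character vector from [read_id_mapping()].
#' @return Character vector of mapped identifiers (order of the mappable
#'   inputs preserved), with attribute `unmapped` holding the dropped
#'   inputs.
#' @export
map_identifiers <- function(symbols, map) {
  hit <- symbols %in% names(map)
  if (any(!hit)) {
    warning(sprintf("map_identifiers: %d identifier(s) had no homolog and were dropped",
                    sum(!hit)), call. = FALSE)
  }
  out <- unname(map[symbols[hit]])
  attr(out, "unmapped") <- symbols[!hit]
  out
}

#' Build a bait-centred interaction network with augmentation
#'
#' Experimental bait--prey edges (a star around the bait, each prey tagged
#' with the region subset it was called in) are unioned with augmentation
#' edges from a reference interaction database, producing a simple
#' undirected graph. An augmentation edge duplicating an experimental one
#' collapses to a single edge carrying both provenance tags; proteins
#' introduced only by augmentation are flagged `augmentation_only`.
#'
#' @param bait Bait gene symbol (upper-cased internally).
#' @param calls Either a call tibble with `gene_symbol` columns and
#'   optionally `region`, a region-set assignment with a `regions` list
#'   column, or a plain character vector of prey symbols.
#' @param augment_edges Optional edge tibble from [read_interactions()].
#' @return An [igraph::graph] with vertex attributes `regions`
#'   (comma-separated region subset, `""` for augmentation-only nodes) and
#'   `augmentation_only`, and edge attributes `provenance`
#'   (`;`-separated tags) and `experimental`.
#' @export
build_network <- function(bait, calls, augment_edges = NULL) {
  if (!is.character(bait) || length(bait) != 1 || !nzchar(bait)) {
    stop_format("bait symbol must be a non-empty string")
  }
  bait <- toupper(bait)
  if (is.data.frame(calls)) {
    if ("regions" %in% names(calls)) {
      prey <- toupper(calls$gene_symbol)
      prey_regions <- vapply(calls$regions, paste, "", collapse = ",")
    } else {
      collapsed <- calls |>
        dplyr::group_by(gene_symbol = toupper(.data$gene_symbol)) |>
        dplyr::summarise(regions = paste(sort(unique(.data$region)), collapse = ","),
                         .groups = "drop")
      prey <- collapsed$gene_symbol
      prey_regions <- collapsed$regions
    }
  } else {
    prey <- toupper(as.character(calls))
    prey_regions <- rep("", length(prey))
  }
  keep <- !duplicated(prey) & prey != bait
  prey <- prey[keep]
  prey_regions <- prey_regions[keep]

  exp_edges <- tibble::tibble(
    a = pmin(rep(bait, length(prey)), prey),
    b = pmax(rep(bait, length(prey)), prey),
    sources = lapply(prey_regions, function(r) {
      paste0("experimental", if (nzchar(r)) paste0(":", r) else "")
    })
  )
  all_edges <- if (is.null(augment_edges) || nrow(augment_edges) == 0) {
    merge_edges(exp_edges)
  } else {
    aug <- augment_edges
    aug$sources <- lapply(aug$sources, function(s) paste0("augmentation:", s))
    merge_edges(dplyr::bind_rows(exp_edges, aug))
  }

  experimental_nodes <- c(bait, prey)
  node_names <- sort(unique(c(experimental_nodes, all_edges$a, all_edges$b)))
  region_of <- stats::setNames(prey_regions, prey)
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = all_edges$a, to = all_edges$b,
      provenance = vapply(all_edges$sources, paste, "", collapse = ";"),
      experimental = vapply(all_edges$sources, function(s) {
        any(startsWith(s, "experimental"))
      }, TRUE)
    ),
    directed = FALSE,
    vertices = data.frame(
      name = node_names,
      regions = ifelse(node_names %in% names(region_of),
                       unname(region_of[node_names]), ""),
      augmentation_only = !(node_names %in% experimental_nodes)
    )
  )
  g
}

#' Topology report for a simple undirected graph
#'
#' Computes the NetworkAnalyzer-style summary statistics: node and edge
#' counts, the degree map, mean neighbors (2E/N), the mean local
#' clustering coefficient, and its expectation under a sparse random
#' uncorrelated network of the same density (mean degree / N), together
#' with their ratio.
#'
#' The local clustering coefficient of a node of degree k is the number of
#' edges among its neighbors divided by k(k-1)/2, defined as 0 for k < 2.
#' By default such nodes are included in the mean (the NetworkAnalyzer
#' convention); set `include_low_degree = FALSE` to average over nodes of
#' degree >= 2 only.
#'
#' @param graph An [igraph::graph], undirected and simple, with >= 1 node.
#' @param include_low_degree Include degree < 2 nodes (as 0) in the mean
#'   clustering coefficient. Default `TRUE`.
#' @return Object of class `topology_report`: list with `n_nodes`,
#'   `n_edges`, `degree` (named integer vector), `mean_neighbors`,
#'   `mean_clustering`, `expected_random_cc`, `cc_ratio`.
#' @export
topology <- function(graph, include_low_degree = TRUE) {
  if (igraph::vcount(graph) == 0) stop_format("topology() requires >= 1 node")
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph, mode = "collapse")
  if (any(igraph::which_loop(graph)) || any(igraph::which_multiple(graph))) {
    graph <- igraph::simplify(graph)
  }
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  stopifnot(sum(deg) == 2 * e)  # handshake lemma
  local_cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  local_cc[deg < 2] <- 0
  mean_cc <- if (include_low_degree) {
    mean(local_cc)
  } else if (any(deg >= 2)) {
    mean(local_cc[deg >= 2])
  } else {
    0
  }
  mean_neighbors <- 2 * e / n
  expected <- mean_neighbors / n
  structure(
    list(
      n_nodes = n, n_edges = e,
      degree = stats::setNames(as.integer(deg), igraph::V(graph)$name),
      mean_neighbors = mean_neighbors,
      mean_clustering = mean_cc,
      expected_random_cc = expected,
      cc_ratio = if (expected > 0) mean_cc / expected else NA_real_
    ),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("nodes %d, edges %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("mean neighbors      %.4f\n", x$mean_neighbors))
  cat(sprintf("mean clustering     %.4f\n", x$mean_clustering))
  cat(sprintf("random expectation  %.4f (ratio %.2f)\n",
              x$expected_random_cc, x$cc_ratio))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' @param graph An [igraph::graph].
#' @param top_n Number of nodes to return (>= 1); capped at the node count.
#' @return Tibble with columns `node`, `degree`, sorted by descending
#'   degree, ties broken lexicographically by node name.
#' @export
top_hubs <- function(graph, top_n = 10) {
  if (top_n < 1) stop_format("top_n must be >= 1")
  deg <- igraph::degree(graph)
  nm <- igraph::V(graph)$name
  ord <- order(-deg, nm)
  take <- utils::head(ord, top_n)
  tibble::tibble(node = nm[take], degree = as.integer(deg[take]))
}

#' @rdname build_network
#' @param graph Graph to export.
#' @param path Output GraphML path.
#' @export
write_graphml <- function(graph, path) {
  igraph::V(graph)$degree <- igraph::degree(graph)
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname topology
#' @param report A `topology_report`.
#' @param path Output JSON path.
#' @export
write_topology_json <- function(report, path) {
  jsonlite::write_json(
    list(n_nodes = report$n_nodes, n_edges = report$n_edges,
         mean_neighbors = report$mean_neighbors,
         mean_clustering = report$mean_clustering,
         expected_random_cc = report$expected_random_cc,
         cc_ratio = report$cc_ratio,
         degree = as.list(report$degree)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
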