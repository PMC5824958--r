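test_that("identifier mapping translates hits and reports drops", {
  map <- c(Camk2a = "CAMK2A", Dlg4 = "DLG4")
  out <- map_identifiers("Camk2a", map)
  expect_equal(as.character(out), "CAMK2A")
  expect_length(attr(out, "unmapped"), 0)

  expect_warning(out2 <- map_identifiers(c("Camk2a", "Zzz9"), map), "dropped")
  expect_equal(as.character(out2), "CAMK2A")
  expect_equal(attr(out2, "unmapped"), "Zzz9")

  out3 <- map_identifiers(character(), map)
  expect_length(out3, 0)
})

test_that("build_network makes a bait star, merges duplicate augmentation edges", {
  calls <- tibble::tibble(gene_symbol = c("A", "B", "C", "D", "E"),
                          region = c("CC", "CC", "HP", "CB", "HP"))
  g <- build_network("ITM2B", calls)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 5)
  expect_false(any(igraph::V(g)$augmentation_only))

  aug <- merge_edges(tibble::tibble(
    a = c("A", "X"), b = c("ITM2B", "Y"),
    sources = list("imex", "imex")
  ))
  g2 <- build_network("ITM2B", calls, aug)
  # duplicate of the experimental ITM2B-A edge collapses, X and Y are new
  expect_equal(igraph::vcount(g2), 8)
  expect_equal(igraph::ecount(g2), 6)
  prov <- igraph::E(g2)$provenance[
    igraph::get_edge_ids(g2, c("ITM2B", "A"))]
  expect_match(prov, "augmentation:imex")
  expect_match(prov, "experimental")
  expect_setequal(igraph::V(g2)$name[igraph::V(g2)$augmentation_only],
                  c("X", "Y"))
  expect_error(build_network("", calls), "bait")
})

test_that("topology computes NetworkAnalyzer-style statistics on closed forms", {
  triangle <- igraph::make_full_graph(3)
  igraph::V(triangle)$name <- c("A", "B", "C")
  t_tri <- topology(triangle)
  expect_equal(t_tri$mean_clustering, 1)
  expect_equal(t_tri$mean_neighbors, 2)

  path3 <- igraph::graph_from_literal(A - B - C)
  t_path <- topology(path3)
  expect_equal(t_path$mean_clustering, 0)

  # any tree has clustering 0; complete graphs have clustering 1
  tree <- igraph::make_tree(15, children = 2, mode = "undirected")
  igraph::V(tree)$name <- paste0("n", 1:15)
  expect_equal(topology(tree)$mean_clustering, 0)
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("n", 1:6)
  expect_equal(topology(k6)$mean_clustering, 1)

  # handshake lemma / identity between the degree map and 2E/N
  sim_g <- igraph::sample_gnm(40, 90)
  igraph::V(sim_g)$name <- paste0("n", 1:40)
  rep <- topology(sim_g)
  expect_equal(sum(rep$degree), 2 * rep$n_edges)
  expect_equal(mean(rep$degree), rep$mean_neighbors, tolerance = 1e-12)
  expect_equal(rep$expected_random_cc, rep$mean_neighbors / rep$n_nodes)
})

test_that("local clustering matches exhaustive triangle enumeration on small graphs", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(4:12, 1)
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < 0.4) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("n", seq_len(n))
    want <- oracle_local_clustering(adj)
    expect_equal(topology(g)$mean_clustering, mean(want), tolerance = 1e-12)
    expect_equal(topology(g, include_low_degree = FALSE)$mean_clustering,
                 if (any(rowSums(adj) >= 2)) mean(want[rowSums(adj) >= 2]) else 0,
                 tolerance = 1e-12)
  }
})

test_that("mean clustering of Erdos-Renyi graphs is near the edge density", {
  n <- 60
  m <- 270  # p = 2E/(N(N-1)) ~ 0.1525, mean degree 9
  p <- 2 * m / (n * (n - 1))
  set.seed(53)
  cc <- replicate(30, {
    g <- igraph::sample_gnm(n, m)
    igraph::V(g)$name <- paste0("n", seq_len(n))
    topology(g)$mean_clustering
  })
  se <- stats::sd(cc) / sqrt(length(cc))
  expect_lt(abs(mean(cc) - p), 3 * se + 1e-3)
})

test_that("hub ranking sorts by degree with lexicographic ties", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("CENTER", paste0("L", 1:6))
  hubs <- top_hubs(star, 3)
  expect_equal(hubs$node[1], "CENTER")
  expect_equal(hubs$degree[1], 6)
  # leaves tie at degree 1 and appear alphabetically
  expect_equal(hubs$node[2:3], c("L1", "L2"))
  expect_error(top_hubs(star, 0), "top_n")
})

test_that("the planted hub ranks first on the generated interaction network", {
  params <- tiny_sim_params(seed = 29)
  sim <- generate_experiment(params)
  res <- generate_reference_resources(params, sim)
  g <- igraph::graph_from_data_frame(res$ppi_edges[, c("a", "b")],
                                     directed = FALSE)
  hubs <- top_hubs(g, 1)
  expect_equal(hubs$node, res$truth$planted_hub)
})

test_that("graphs export to GraphML with degree attributes", {
  calls <- tibble::tibble(gene_symbol = c("A", "B"), region = c("CC", "HP"))
  g <- build_network("ITM2B", calls)
  path <- tempfile(fileext = ".graphml")
  write_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_setequal(igraph::V(back)$name, c("ITM2B", "A", "B"))
  expect_equal(sort(igraph::V(back)$degree), c(1, 1, 2))
})
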