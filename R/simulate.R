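#' Parameters for the synthetic co-IP experiment generator
#'
#' Defines the study conditions the generator emulates: a bait co-IP with
#' two mock negative controls, run in three brain regions with three
#' replicates each, producing integer PSM counts. Planted true interactors
#' have bait counts elevated by `ratio_effect`; sticky background binders
#' have comparable means in bait and mocks; contaminants (keratins) appear
#' in every channel.
#'
#' @param n_true_ratio Planted interactors detectable by the bait:mock
#'   ratio (present in mocks at low level). Default 40.
#' @param n_true_bait_only Planted interactors never present in mocks.
#'   Default 20.
#' @param n_background Sticky background proteins (bait:mock ratio ~ 1).
#'   Default 120.
#' @param n_contaminants Contaminant proteins spiked into all channels
#'   (drawn from the keratin list, then synthetic names). Default 10.
#' @param bait_mean,mock_mean Poisson means for PSM counts: baseline bait
#'   abundance and mock-carryover of true interactors. Defaults 8 and 2.
#' @param ratio_effect Multiplier on `bait_mean` for planted
#'   ratio-detectable interactors. Default 4.
#' @param regions Region codes used. Default all of [coip_regions()].
#' @param replicates Independent replicates per region. Default 3.
#' @param brain_enriched_fraction Fraction of non-contaminant proteins
#'   marked brain-enriched in the synthetic tissue catalog. Default 0.25.
#' @param n_terms Background annotation terms. Default 25.
#' @param term_size_range Size range of background terms. Default c(10, 40).
#' @param planted_term_size,planted_term_overlap Size of the planted
#'   over-represented term and how many planted interactors it contains.
#'   Defaults 30 and 20.
#' @param n_reference_genes Size of the reference (universe) gene set,
#'   including all emitted proteins. Default 2000.
#' @param ppi_n_nodes,ppi_edge_prob Erdos-Renyi background interaction
#'   network. Defaults 100 nodes, edge probability 0.04.
#' @param planted_hub_degree Degree of the planted hub in the background
#'   network. Default 25.
#' @param dispersion If non-`NULL`, counts are negative binomial with this
#'   size parameter (overdispersion stress test) instead of Poisson.
#' @param seed Integer seed; one seed drives all generators through
#'   derived per-stage streams, so outputs are byte-identical across runs.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_true_ratio = 40, n_true_bait_only = 20,
                       n_background = 120, n_contaminants = 10,
                       bait_mean = 8, mock_mean = 2, ratio_effect = 4,
                       regions = coip_regions(), replicates = 3,
                       brain_enriched_fraction = 0.25,
                       n_terms = 25, term_size_range = c(10, 40),
                       planted_term_size = 30, planted_term_overlap = 20,
                       n_reference_genes = 2000,
                       ppi_n_nodes = 100, ppi_edge_prob = 0.04,
                       planted_hub_degree = 25,
                       dispersion = NULL, seed = 1L) {
  p <- list(
    n_true_ratio = n_true_ratio, n_true_bait_only = n_true_bait_only,
    n_background = n_background, n_contaminants = n_contaminants,
    bait_mean = bait_mean, mock_mean = mock_mean, ratio_effect = ratio_effect,
    regions = regions, replicates = as.integer(replicates),
    brain_enriched_fraction = brain_enriched_fraction,
    n_terms = n_terms, term_size_range = term_size_range,
    planted_term_size = planted_term_size,
    planted_term_overlap = planted_term_overlap,
    n_reference_genes = n_reference_genes,
    ppi_n_nodes = ppi_n_nodes, ppi_edge_prob = ppi_edge_prob,
    planted_hub_degree = planted_hub_degree,
    dispersion = dispersion, seed = as.integer(seed)
  )
  counts <- c("n_true_ratio", "n_true_bait_only", "n_background",
              "n_contaminants", "replicates", "n_terms", "planted_term_size",
              "planted_term_overlap", "ppi_n_nodes", "planted_hub_degree")
  for (f in counts) {
    if (p[[f]] < 0 || p[[f]] != floor(p[[f]])) {
      stop_format("%s must be a non-negative integer", f)
    }
  }
  if (p$bait_mean <= 0 || p$mock_mean <= 0 || p$ratio_effect <= 0) {
    stop_format("bait_mean, mock_mean and ratio_effect must be positive")
  }
  if (p$brain_enriched_fraction < 0 || p$brain_enriched_fraction > 1 ||
      p$ppi_edge_prob < 0 || p$ppi_edge_prob > 1) {
    stop_format("probabilities must lie in [0, 1]")
  }
  if (p$planted_term_overlap > p$planted_term_size) {
    stop_format("planted_term_overlap (%d) exceeds planted_term_size (%d)",
                p$planted_term_overlap, p$planted_term_size)
  }
  if (!all(p$regions %in% coip_regions()) || length(p$regions) == 0) {
    stop_format("regions must be a non-empty subset of %s",
                paste(coip_regions(), collapse = ", "))
  }
  if (p$replicates < 1) stop_format("replicates must be >= 1")
  structure(p, class = "sim_params")
}

# One shared seed drives all generators through derived per-stage streams,
# so resources can be regenerated independently yet reproducibly.
derive_seed <- function(seed, stage) {
  offsets <- c(experiment = 101L, tissue = 211L, annotation = 307L,
               ppi = 401L, mapping = 503L)
  stopifnot(stage %in% names(offsets))
  as.integer((abs(as.numeric(seed)) * 2654435 + offsets[[stage]]) %% 2147483647)
}

# zero-truncated count draw: planted interactors are present in the bait
# channel of every replicate by construction
rcount_pos <- function(n, mean, dispersion) {
  if (n == 0) return(integer())
  u <- stats::runif(n)
  if (is.null(dispersion)) {
    p0 <- stats::dpois(0, mean)
    stats::qpois(p0 + u * (1 - p0), mean)
  } else {
    p0 <- stats::dnbinom(0, size = dispersion, mu = mean)
    stats::qnbinom(p0 + u * (1 - p0), size = dispersion, mu = mean)
  }
}

rcount <- function(n, mean, dispersion) {
  if (n == 0) return(integer())
  if (is.null(dispersion)) stats::rpois(n, mean)
  else stats::rnbinom(n, size = dispersion, mu = mean)
}

random_region_subset <- function(n, regions) {
  lapply(seq_len(n), function(i) {
    size <- sample.int(length(regions), 1)
    sort(sample(regions, size))
  })
}

#' Generate a synthetic co-IP PSM experiment with planted truth
#'
#' Emits a PSM table covering every (region, channel, replicate) cell of
#' the design, plus the ground truth of what was planted. Draws of zero
#' are emitted as absent rows (no row), exercising the caller's
#' absence-equals-zero semantics. Planted interactors receive a random
#' non-empty region subset; background binders and contaminants are
#' present in all regions.
#'
#' @param params A [sim_params()].
#' @return List with elements `psm` (tibble in [read_psm_table()] layout),
#'   `truth` (list: `ratio_interactors`, `bait_only_interactors` — tibbles
#'   with `accession`, `gene_symbol`, `regions`; `background`,
#'   `contaminants` — character vectors) and `contaminants` (the
#'   generator's own contaminant list, for [filter_contaminants()]).
#' @export
generate_experiment <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, "experiment"))
  p <- params

  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  sym_ratio <- mk("Rint", p$n_true_ratio)
  sym_bonly <- mk("Bint", p$n_true_bait_only)
  sym_bkg <- mk("Bkg", p$n_background)
  keratins <- keratin_contaminants()
  sym_cont <- if (p$n_contaminants <= length(keratins)) {
    keratins[seq_len(p$n_contaminants)]
  } else {
    c(keratins, mk("Cont", p$n_contaminants - length(keratins)))
  }
  all_sym <- c(sym_ratio, sym_bonly, sym_bkg, sym_cont)
  acc <- stats::setNames(sprintf("S%05d", seq_along(all_sym)), all_sym)

  reg_ratio <- random_region_subset(p$n_true_ratio, p$regions)
  reg_bonly <- random_region_subset(p$n_true_bait_only, p$regions)

  rows <- list()
  emit <- function(symbols, region, channel, replicate, counts) {
    keep <- counts > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(
      accession = unname(acc[symbols[keep]]),
      gene_symbol = symbols[keep],
      region = region, channel = channel,
      replicate = as.integer(replicate), psm = as.integer(counts[keep])
    )
  }
  for (reg in p$regions) {
    in_ratio <- sym_ratio[vapply(reg_ratio, function(r) reg %in% r, TRUE)]
    in_bonly <- sym_bonly[vapply(reg_bonly, function(r) reg %in% r, TRUE)]
    for (rep_i in seq_len(p$replicates)) {
      rows <- c(rows, list(
        emit(in_ratio, reg, "bait", rep_i,
             rcount_pos(length(in_ratio), p$ratio_effect * p$bait_mean, p$dispersion)),
        emit(in_ratio, reg, "mock_beads", rep_i,
             rcount(length(in_ratio), p$mock_mean, p$dispersion)),
        emit(in_ratio, reg, "mock_igg", rep_i,
             rcount(length(in_ratio), p$mock_mean, p$dispersion)),
        emit(in_bonly, reg, "bait", rep_i,
             rcount_pos(length(in_bonly), p$bait_mean, p$dispersion)),
        emit(sym_bkg, reg, "bait", rep_i,
             rcount(length(sym_bkg), p$bait_mean, p$dispersion)),
        emit(sym_bkg, reg, "mock_beads", rep_i,
             rcount(length(sym_bkg), p$bait_mean, p$dispersion)),
        emit(sym_bkg, reg, "mock_igg", rep_i,
             rcount(length(sym_bkg), p$bait_mean, p$dispersion)),
        emit(sym_cont, reg, "bait", rep_i,
             rcount(length(sym_cont), p$bait_mean, p$dispersion)),
        emit(sym_cont, reg, "mock_beads", rep_i,
             rcount(length(sym_cont), p$bait_mean, p$dispersion)),
        emit(sym_cont, reg, "mock_igg", rep_i,
             rcount(length(sym_cont), p$bait_mean, p$dispersion))
      ))
    }
  }
  psm <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$region, .data$channel, .data$replicate, .data$accession)
  truth <- list(
    ratio_interactors = tibble::tibble(
      accession = unname(acc[sym_ratio]), gene_symbol = sym_ratio,
      regions = reg_ratio),
    bait_only_interactors = tibble::tibble(
      accession = unname(acc[sym_bonly]), gene_symbol = sym_bonly,
      regions = reg_bonly),
    background = sym_bkg,
    contaminants = sym_cont
  )
  list(psm = psm, truth = truth, contaminants = sym_cont)
}

#' Generate the reference resources the downstream stages consume
#'
#' Builds, from the same seed stream as the experiment: a three-source
#' tissue catalog with a planted brain-enriched subset; an annotation
#' catalog (GMT-shaped) of background terms plus one planted term
#' overlapping the planted interactors; an Erdos-Renyi background
#' interaction network with one planted hub; and an identifier homology
#' map covering every emitted symbol (rat-style symbol to upper-cased
#' human-style homolog).
#'
#' @param params A [sim_params()].
#' @param experiment Result of [generate_experiment()] under the same
#'   params.
#' @return List with `tissue_catalog`, `annotation_catalog`, `ppi_edges`,
#'   `id_map`, `reference_genes` and `truth` (list: `brain_enriched`,
#'   `planted_term_id`, `planted_hub`).
#' @export
generate_reference_resources <- function(params, experiment) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  proteins <- unique(experiment$psm$gene_symbol)
  planted <- c(experiment$truth$ratio_interactors$gene_symbol,
               experiment$truth$bait_only_interactors$gene_symbol)
  non_contaminant <- setdiff(proteins, experiment$truth$contaminants)

  # identifier map: every emitted symbol has an upper-cased homolog
  set.seed(derive_seed(p$seed, "mapping"))
  id_map <- stats::setNames(toupper(proteins), proteins)

  # tissue catalog with planted brain-enriched subset
  set.seed(derive_seed(p$seed, "tissue"))
  n_enriched <- round(p$brain_enriched_fraction * length(non_contaminant))
  enriched <- sort(sample(non_contaminant, n_enriched))
  cats <- tissue_qualifying_categories()
  entries <- lapply(enriched, function(g) {
    srcs <- sample(names(cats), sample.int(3, 1))
    tibble::tibble(
      source = srcs,
      gene_symbol = toupper(g),
      category = vapply(srcs, function(s) {
        cs <- cats[[s]]
        cs[sample.int(length(cs), 1)]
      }, "")
    )
  })
  tissue_catalog <- validate_tissue_catalog(dplyr::bind_rows(entries))

  # annotation catalog over a reference universe containing all proteins
  set.seed(derive_seed(p$seed, "annotation"))
  universe <- unique(c(toupper(proteins),
                       sprintf("GENE%04d", seq_len(p$n_reference_genes))))
  planted_up <- toupper(planted)
  overlap <- sample(planted_up, min(p$planted_term_overlap, length(planted_up)))
  filler <- sample(setdiff(universe, planted_up),
                   p$planted_term_size - length(overlap))
  planted_term <- tibble::tibble(
    term_id = "TERM:PLANTED", name = "planted over-represented term",
    genes = list(sort(unique(c(overlap, filler))))
  )
  background_terms <- lapply(seq_len(p$n_terms), function(i) {
    size <- sample(seq(p$term_size_range[1], p$term_size_range[2]), 1)
    tibble::tibble(term_id = sprintf("TERM:%04d", i),
                   name = sprintf("background term %d", i),
                   genes = list(sort(sample(universe, size))))
  })
  annotation_catalog <- dplyr::bind_rows(c(background_terms, list(planted_term)))

  # background PPI with a planted hub
  set.seed(derive_seed(p$seed, "ppi"))
  ppi_nodes <- unique(c(toupper(planted),
                        sample(universe, max(0, p$ppi_n_nodes - length(planted)))))
  hub <- sample(toupper(planted), 1)
  pairs <- utils::combn(ppi_nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p$ppi_edge_prob
  er_edges <- tibble::tibble(a = pairs[1, keep], b = pairs[2, keep],
                             sources = as.list(rep("simulated_er", sum(keep))))
  hub_partners <- sample(setdiff(ppi_nodes, hub),
                         min(p$planted_hub_degree, length(ppi_nodes) - 1))
  hub_edges <- tibble::tibble(a = rep(hub, length(hub_partners)),
                              b = hub_partners,
                              sources = as.list(rep("simulated_hub",
                                                    length(hub_partners))))
  ppi_edges <- merge_edges(dplyr::bind_rows(er_edges, hub_edges))

  list(
    tissue_catalog = tissue_catalog,
    annotation_catalog = annotation_catalog,
    ppi_edges = ppi_edges,
    id_map = id_map,
    reference_genes = universe,
    truth = list(brain_enriched = toupper(enriched),
                 planted_term_id = "TERM:PLANTED",
                 planted_hub = hub)
  )
}

#' Write a simulated experiment and its resources to disk
#'
#' Emits the exact file formats the readers consume: `psm.tsv`,
#' `contaminants.txt`, `tissue.tsv`, `annotations.gmt`, `ppi_edges.tsv`,
#' `id_map.tsv`, `reference_genes.txt` and `truth.json`.
#'
#' @param params A [sim_params()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_inputs <- function(params = sim_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  experiment <- generate_experiment(params)
  resources <- generate_reference_resources(params, experiment)
  paths <- list(
    psm = file.path(dir, "psm.tsv"),
    contaminants = file.path(dir, "contaminants.txt"),
    tissue = file.path(dir, "tissue.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    id_map = file.path(dir, "id_map.tsv"),
    reference = file.path(dir, "reference_genes.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_psm_table(experiment$psm, paths$psm)
  writeLines(experiment$contaminants, paths$contaminants)
  write_tissue_catalog(resources$tissue_catalog, paths$tissue)
  write_gmt(resources$annotation_catalog, paths$gmt)
  write_interactions(resources$ppi_edges, paths$ppi)
  writeLines(paste(names(resources$id_map), resources$id_map, sep = "\t"),
             paths$id_map)
  writeLines(resources$reference_genes, paths$reference)
  jsonlite::write_json(
    list(
      ratio_interactors = experiment$truth$ratio_interactors$gene_symbol,
      bait_only_interactors = experiment$truth$bait_only_interactors$gene_symbol,
      background = experiment$truth$background,
      contaminants = experiment$truth$contaminants,
      brain_enriched = resources$truth$brain_enriched,
      planted_term_id = resources$truth$planted_term_id,
      planted_hub = resources$truth$planted_hub
    ),
    paths$truth, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
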