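#!/usr/bin/env Rscript
# Stage 4: annotation over-representation of the ES interactome.
#
# One-sided hypergeometric test of every catalog term against the mapped
# ES query, relative to the simulated reference universe; terms with
# p < 0.05 are flagged (no correction, with Benjamini-Hochberg available
# as an option). The generated catalog contains one planted term that a
# correct engine must rank first.

suppressPackageStartupMessages(library(coipnet))

if (!file.exists("results/calls.tsv")) {
  stop("run analysis/02_call_interactors.R first", call. = FALSE)
}
calls <- read_calls("results/calls.tsv")
tissue <- read_tissue_catalog("results/sim/tissue.tsv")
catalog <- read_gmt("results/sim/annotations.gmt")
reference <- readLines("results/sim/reference_genes.txt")
id_map <- read_id_mapping("results/sim/id_map.tsv")
truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)

es <- classify_es(unique(calls$gene_symbol), tissue)
query <- map_identifiers(intersect(unique(calls$gene_symbol),
                                   names(id_map)), id_map)
query <- intersect(query, es_subset(es))

res <- enrich(query, catalog, reference, alpha = 0.05, correction = "none")
readr::write_tsv(res, "results/enrichment.tsv", progress = FALSE)

cat("Tested", nrow(res), "terms with >= 1 hit;",
    sum(res$significant), "significant at p < 0.05\n")
cat("Top term:", res$term_id[1],
    sprintf("(k=%d, K=%d, %%assoc=%.1f, fold=%.1f, p=%.3g)\n",
            res$k[1], res$K[1], res$pct_associated[1], res$fold[1], res$p[1]))
cat("Planted term", truth$planted_term_id,
    if (res$term_id[1] == truth$planted_term_id) "ranked first\n"
    else "NOT first -- inspect results/enrichment.tsv\n")
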