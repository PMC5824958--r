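#!/usr/bin/env Rscript
# Stage 1: generate the synthetic co-IP experiment and reference resources.
#
# Emulates the study design the downstream stages assume: a single bait
# pulled down in three brain regions (CC, HP, CB), each with one bait
# co-IP and two mock controls, three replicates; planted ratio-detectable
# interactors (bait counts elevated 4x over a baseline Poisson mean of 8),
# planted bait-only interactors, sticky background binders with equal
# means in bait and mocks, and keratin contaminants in every channel.

suppressPackageStartupMessages(library(coipnet))

params <- sim_params(seed = 20260927)
paths <- simulate_inputs(params, "results/sim")

psm <- read_psm_table(paths$psm)
cat("Simulated PSM table:", nrow(psm), "rows covering",
    length(unique(psm$accession)), "proteins\n")
cat("Planted: ", params$n_true_ratio, "ratio-detectable +",
    params$n_true_bait_only, "bait-only interactors;",
    params$n_background, "background binders;",
    params$n_contaminants, "contaminants\n")
cat("Inputs written under results/sim/\n")
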