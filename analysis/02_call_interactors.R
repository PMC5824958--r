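#!/usr/bin/env Rscript
# Stage 2: call interactors per region from the simulated PSM tables and
# remove contaminants.
#
# The calling rule keeps a bait-channel protein if it never appears in a
# mock control (bait_only) or if its bait:mock PSM ratio is >= 2.0
# (ratio_pass; mock denominator = max over the two mocks). Replicates
# combine by union.

suppressPackageStartupMessages(library(coipnet))

if (!file.exists("results/sim/psm.tsv")) {
  stop("run analysis/01_simulate.R first", call. = FALSE)
}
psm <- read_psm_table("results/sim/psm.tsv")
contaminants <- read_contaminants("results/sim/contaminants.txt")
truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)

calls <- call_interactors(psm, call_config())
filtered <- filter_contaminants(calls, contaminants)
write_calls(filtered, "results/calls.tsv")

planted <- c(truth$ratio_interactors, truth$bait_only_interactors)
called_sym <- unique(filtered$gene_symbol)
cat("Called", length(unique(calls$accession)), "proteins;",
    attr(filtered, "n_removed"), "contaminant call(s) removed\n")
cat("Evidence classes:\n")
print(table(filtered$evidence_class))
cat(sprintf("Recall on planted interactors: %.3f\n",
            mean(planted %in% called_sym)))
cat(sprintf("Precision against background:  %.3f\n",
            mean(called_sym %in% planted)))
cat("Calls written to results/calls.tsv\n")
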