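---
title: "Methods: interactor calling and interactome characterisation in coipnet"
author: "coipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactor calling and interactome characterisation in coipnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipnet)
```

## The problem

Affinity purification of a bait protein followed by mass spectrometry
(AP-MS / co-IP-MS) recovers the bait together with everything that
co-precipitates with it — true binding partners, but also proteins that
stick to the beads or the antibody. The semi-quantitative currency of
such experiments is the peptide-spectrum-match (PSM) count per protein.
coipnet implements the analysis chain used to turn such counts into a
characterised interactome for a brain-expressed bait (BRI2/ITM2B being
the packaged worked example): interactor calling against mock controls,
contaminant removal, brain tissue-enrichment classification, region
Venn partitioning, annotation over-representation, and interaction
network construction with topology statistics.

## Interactor calling

For each brain region and replicate the design has one bait co-IP and
two mock controls (beads only; beads + nonspecific IgG). A protein seen
in the bait channel is called an interactor iff

* it never appears in either mock (**bait_only** evidence), or
* it appears in a mock but its PSM ratio bait / agg(mock) is at least
  2.0 (**ratio_pass** evidence). The boundary is inclusive: a ratio of
  exactly 2.0 is kept.

Three choices the rule statement leaves open are exposed in
`call_config()` rather than guessed:

* **Mock aggregation** (`mock_aggregation`): with the protein present in
  both mocks, the denominator is the maximum of the two counts by
  default — the most conservative reading — with `sum` and `mean`
  available for sensitivity analysis. A protein present in exactly one
  mock uses that mock's count.
* **Replicate combination** (`min_replicate_support`): replicates
  combine by union by default (a protein called in any replicate is
  kept, with its support set recorded); requiring support in 2 or 3
  replicates is a config switch. Raising either threshold can only
  remove calls, never add them — a property the tests assert.
* **Mixed evidence**: a protein bait-only in one replicate and
  ratio-passing in another resolves to `ratio_pass` (the stronger,
  quantitative evidence) carrying the maximum ratio.

Absence and a count of zero are deliberately equivalent: a mock count of
zero cannot produce a division by zero, it produces bait-only evidence.

Contaminant filtering removes, case-insensitively by symbol or
accession, anything on a contaminant list; the packaged default is the
fifteen hair/skin keratins (`keratin_contaminants()`) that are standard
exclusions in co-IP work.

## Tissue-enrichment (ES) classification

A called interactor is classified brain **enriched/specific (ES)** by
joining against a three-source expression catalog modelled on the
public resources used for this purpose: HPA-style protein-evidence
categories ("Tissue enriched", "Tissue enhanced", "Group enriched"),
TiGER-style EST brain-preferential expression, and UniGene-style
brain-restricted expression. No combination rule is given in the
sources this models, so `classify_es()` defaults to the **union** (a
protein qualifies if any source lists it) — the inclusive reading — with
`intersection` available for sensitivity analysis. Matching is by
upper-cased gene symbol so rat (`Camk2a`) and human (`CAMK2A`)
conventions join; accessions are carried verbatim as metadata.

## Region Venn partitioning

`venn_partition()` decomposes the proteins by their exact region
membership pattern over cerebral cortex (CC), hippocampus (HP) and
cerebellum (CB) into the seven disjoint Venn cells. The partition is
computed from each protein's region *set*, never from parallel
per-region lists, so double counting is structurally impossible: the
cells are disjoint and their union is the input by construction. Region
totals are always the sum of the four cells containing the region.

The packaged 120-protein ES interactome table reproduces the published
cell sizes exactly (31/14/8 region-specific, 21/17/2 pairwise, 27
triple). For the published full 511-protein interactome the printed
cells (108/62/85/80/61/23/92) sum to 511 and give a hippocampus total
of 257, both matching the printed totals — but they give 341 for the
cortex and 261 for the cerebellum where 342 and 262 are printed. The
±1 discrepancies cannot be resolved from the main text (isoform or
duplicate accounting in the source supplementary list is a plausible
cause); coipnet therefore always reports totals computed from cells and
does not attempt to reproduce the two irreconcilable printed numbers.

## Over-representation statistics

`enrich()` scores each annotation term by the upper-tail hypergeometric
probability $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, with
$N$ the reference (universe) size, $K$ the term size within the
reference, $n$ the query size and $k$ the observed hits — computed via
`stats::phyper`, with an exhaustive-enumeration oracle in the test
suite for all $N \le 12$ and a pmf-normalisation check at $10^{-12}$.
Alongside $p$ it reports the two descriptive statistics customary in
proteomics enrichment tables: percent associated genes $100\,k/K$ and
fold enrichment $(k/n)/(K/N)$.

Numerical and interface choices:

* default is **no correction at $\alpha = 0.05$** — the classical
  criterion the modelled analyses state — with Benjamini–Hochberg
  offered because modern practice expects it; BH can only flag fewer
  terms at the same $\alpha$, which the tests assert;
* terms with $k = 0$ carry no over-representation evidence and are
  omitted; the BH denominator is the number of emitted terms;
* ties in $p$ break by `term_id`, making output order deterministic;
* query genes absent from the reference are dropped with a warning
  rather than silently inflating $n$; catalog genes outside the
  reference do not count toward $K$.

## Network construction and topology

`build_network()` unions the experimental bait–prey star (each prey
tagged with its region subset) with augmentation edges from a reference
interaction database (file-based: an `a b source` TSV or the
identifier columns of PSI-MITAB 2.5). Self-loops are dropped at parse —
the topology formulas assume simple graphs — and duplicate unordered
pairs merge keeping the union of provenance, so an augmentation edge
duplicating an experimental one collapses into a single edge with both
tags. Proteins introduced only by augmentation are flagged
`augmentation_only`. Cross-species joins go through a homology mapping
table; identifiers without a homolog are dropped with a logged count,
mirroring the losses inherent to homology extrapolation.

`topology()` reports NetworkAnalyzer-compatible statistics:

* **mean neighbors** $2E/N$ (equal to the mean of the degree map, an
  identity asserted at $10^{-12}$, with the handshake lemma checked on
  every call);
* **mean clustering coefficient**: the local coefficient of a node of
  degree $k$ is triangles$/\binom{k}{2}$, defined 0 for $k < 2$; such
  nodes are *included* in the mean by default (the convention of the
  desktop tool this models), with `include_low_degree = FALSE` to
  exclude them;
* the sparse random-graph expectation $\langle k \rangle / N$ and the
  ratio of observed to expected clustering.

Note that $\langle k \rangle / N$ for a 144-node, 286-edge network is
$\approx 0.028$, not the 0.02 printed in the modelled analysis, whose
clustering ratio (4.5×) is therefore not reproduced here; likewise its
cortex network's printed mean neighbors (2.243 at 292 nodes / 330
edges) differs from $2E/N = 2.260$, possibly from multigraph or
self-loop handling in the original tool. coipnet computes the
closed-form identities and leaves those two printed values documented
rather than imitated. The identities that do reconcile are reproduced
exactly: $2 \cdot 286 / 144 = 3.972$, $2 \cdot 165/160 = 2.0625$ and
$2 \cdot 47/47 = 2.0$.

Hub ranking (`top_hubs()`) sorts by descending degree with
lexicographic tie-breaks for determinism.

## The synthetic-data generator

All stages are testable without downloads because `sim_params()` /
`generate_experiment()` / `generate_reference_resources()` generate
every input with planted ground truth:

* **Counts** are Poisson by default (the simplest integer count model),
  with a negative-binomial switch (`dispersion`) for overdispersion
  stress tests. Planted ratio-detectable interactors draw bait counts
  at mean `ratio_effect * bait_mean` (defaults 4 × 8) and mock counts
  at `mock_mean` (default 2); bait-only interactors appear in the bait
  channel only; background binders have equal means in bait and mocks;
  contaminants (keratin symbols) appear in every channel.
* Planted interactors' bait counts are **zero-truncated**, so every
  planted protein is present in the bait channel of each replicate — a
  consistency requirement between the truth record and the emitted
  tables. At the default means the truncation shifts the mean by less
  than 0.01 and is accounted for in the moment-recovery test.
* Draws of zero are emitted as **absent rows**, exercising the caller's
  absence-equals-zero semantics.
* Planted interactors receive random non-empty region subsets (region
  Venn structure); background and contaminants appear in all regions.
* Resources: a tissue catalog marking a `brain_enriched_fraction`
  (default 0.25) of non-contaminant proteins across one to three
  sources; an annotation catalog of background terms plus one planted
  term overlapping the planted interactors (20 of a 30-gene term by
  default); an Erdős–Rényi background interaction network (100 nodes,
  edge probability 0.04) with one planted hub of degree 25; and an
  identifier map covering every emitted symbol.
* **One seed drives everything** through derived per-stage streams, so
  any resource can be regenerated independently and all outputs are
  byte-identical across runs.

Default sizes (40 ratio + 20 bait-only planted interactors, 120
background binders, 10 contaminants, 3 regions × 3 replicates, a
2000-gene reference) keep a full pipeline run in the hundreds of
milliseconds while leaving every rate away from 0 and 1; the test suite
uses a smaller variant (15/8/40/5) for speed, and the moment and
fraction-recovery checks scale n up to 10⁴ where standard errors are
informative.

What the generator does **not** emulate: realistic protein abundance
distributions, correlated mock/bait noise, peptide-level identification
or FDR, shared peptides, or biologically structured interaction
networks. Passing tests on synthetic data therefore demonstrate the
correctness of the decision rules and statistics, not their power or
error rates on real co-IP data.

## Degenerate inputs and numerical conventions

* Empty interaction files parse to empty edge sets (not errors); an
  empty contaminant list is the identity filter; an empty tissue
  catalog warns and classifies nothing ES.
* An empty region set on any protein is a validation error naming the
  protein; unknown region or channel codes are rejected at parse with
  the allowed codes listed.
* A reference-free enrichment call is a domain error; a query disjoint
  from every term yields an empty (not failing) result.
* `topology()` requires at least one node; graphs are coerced to
  simple undirected form before any metric is computed.
* All file writers are deterministic; re-running a stage on unchanged
  inputs overwrites outputs with identical bytes.

## Worked example and reproduction

The `analysis/` directory holds the five-stage workflow (simulate,
call, tissue + Venn, enrichment, network) as narrative scripts over the
package functions, and `scripts/acceptance.R` recomputes the seven Venn
cells of the packaged 120-protein table from scratch. See the README
for the exact commands and the output they print.
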