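# Independent brute-force oracles, kept deliberately literal and separate
# from the implementation paths they check.

# Upper-tail hypergeometric by exhaustive enumeration of the pmf.
oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Literal per-replicate calling rule, enumerating every protein.
oracle_call_replicate <- function(bait, mocks, min_ratio = 2,
                                  agg = c("max", "sum", "mean")) {
  agg <- match.arg(agg)
  aggf <- switch(agg, max = max, sum = sum, mean = mean)
  called <- character()
  class <- character()
  for (acc in names(bait)) {
    b <- bait[[acc]]
    if (is.na(b) || b == 0) next
    mvals <- c()
    for (m in mocks) {
      v <- if (acc %in% names(m)) m[[acc]] else 0
      if (!is.na(v) && v > 0) mvals <- c(mvals, v)
    }
    if (length(mvals) == 0) {
      called <- c(called, acc); class <- c(class, "bait_only")
    } else if (b / aggf(mvals) >= min_ratio) {
      called <- c(called, acc); class <- c(class, "ratio_pass")
    }
  }
  data.frame(accession = called, evidence_class = class,
             stringsAsFactors = FALSE)
}

# Local clustering coefficients by exhaustive neighbor-pair enumeration
# over an adjacency matrix.
oracle_local_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (adj[nb[i], nb[j]] > 0) links <- links + 1
      }
    }
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

# Venn cells by independent set algebra on per-region membership sets.
oracle_venn <- function(ids, region_sets) {
  in_reg <- function(r) ids[vapply(region_sets, function(s) r %in% s, TRUE)]
  cc <- in_reg("CC"); hp <- in_reg("HP"); cb <- in_reg("CB")
  list(
    cc_only = sort(setdiff(cc, union(hp, cb))),
    hp_only = sort(setdiff(hp, union(cc, cb))),
    cb_only = sort(setdiff(cb, union(cc, hp))),
    cc_hp = sort(setdiff(intersect(cc, hp), cb)),
    cc_cb = sort(setdiff(intersect(cc, cb), hp)),
    hp_cb = sort(setdiff(intersect(hp, cb), cc)),
    all_three = sort(intersect(intersect(cc, hp), cb))
  )
}

# Small random named count vector ("absent" proteins simply missing).
random_counts <- function(proteins, max_count = 10) {
  n <- length(proteins)
  counts <- sample(0:max_count, n, replace = TRUE)
  keep <- counts > 0
  stats::setNames(counts[keep], proteins[keep])
}

tiny_sim_params <- function(seed = 42, ...) {
  sim_params(n_true_ratio = 15, n_true_bait_only = 8, n_background = 40,
             n_contaminants = 5, n_terms = 10, n_reference_genes = 500,
             ppi_n_nodes = 60, seed = seed, ...)
}
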