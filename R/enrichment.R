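#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a draw
#' of `n` genes from a reference of `N` (of which `K` are annotated to the
#' term) contains at least `k` annotated genes. This is the standard
#' over-representation p-value. Computed via [stats::phyper()], which is
#' numerically stable for reference sizes well beyond 1e5.
#'
#' @param k Observed hits in the query (vectorized).
#' @param K Term size in the reference.
#' @param n Query size.
#' @param N Reference size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(K, n, N) < 0) || K > N || n > N) {
    stop_format("require 0 <= K <= N and 0 <= n <= N (got K=%s, n=%s, N=%s)", K, n, N)
  }
  if (any(k < 0) || any(k > pmin(n, K))) {
    stop_format("require 0 <= k <= min(n, K)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotation-term over-representation analysis
#'
#' One-sided hypergeometric test of each catalog term against a query gene
#' set, relative to a reference (universe) set. Alongside the p-value the
#' two descriptive statistics customary in proteomics enrichment tables
#' are reported: percent associated genes (100 k / K) and fold enrichment
#' ((k/n) / (K/N)).
#'
#' Terms with no query hit (k = 0) carry no over-representation evidence
#' and are omitted; the Benjamini-Hochberg denominator is the number of
#' emitted terms. Query genes absent from the reference are dropped with a
#' warning rather than silently inflating the query size. Catalog genes
#' outside the reference do not count towards K.
#'
#' @param query Character vector of query gene symbols.
#' @param catalog Annotation catalog tibble from [read_gmt()].
#' @param reference Character vector: the reference (universe) gene set.
#' @param alpha Significance level in (0, 1]; default 0.05.
#' @param correction `"none"` (default, the classical p < alpha criterion)
#'   or `"benjamini_hochberg"`.
#' @return Tibble sorted by ascending p then `term_id`, with columns
#'   `term_id`, `name`, `k`, `n`, `K`, `N`, `pct_associated`, `fold`, `p`,
#'   `p_adj`, `significant`.
#' @export
enrich <- function(query, catalog, reference, alpha = 0.05,
                   correction = c("none", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_format("alpha must be in (0, 1]")
  }
  reference <- unique(toupper(reference))
  if (length(reference) == 0) stop_format("empty reference set")
  query <- unique(toupper(query))
  outside <- setdiff(query, reference)
  if (length(outside) > 0) {
    warning(sprintf("dropped %d query gene(s) absent from the reference",
                    length(outside)), call. = FALSE)
    query <- setdiff(query, outside)
  }
  n <- length(query)
  N <- length(reference)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    genes <- intersect(catalog$genes[[i]], reference)
    K <- length(genes)
    k <- length(intersect(genes, query))
    if (k == 0) return(NULL)
    tibble::tibble(
      term_id = catalog$term_id[i], name = catalog$name[i],
      k = k, n = n, K = K, N = N,
      pct_associated = 100 * k / K,
      fold = (k / n) / (K / N),
      p = hypergeom_upper_tail(k, K, n, N)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(term_id = character(), name = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), pct_associated = numeric(),
                          fold = numeric(), p = numeric())
  }
  out$p_adj <- if (correction == "benjamini_hochberg") {
    stats::p.adjust(out$p, method = "BH")
  } else {
    out$p
  }
  out$significant <- out$p_adj < alpha
  out[order(out$p, out$term_id), ]
}
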