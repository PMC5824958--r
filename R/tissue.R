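#' Classify proteins as brain enriched/specific (ES)
#'
#' Joins a protein list against a three-source tissue-expression catalog
#' (HPA-style protein-evidence categories, TiGER-style EST preferential
#' expression, UniGene-style restricted expression). In `union` mode
#' (default) a protein is ES if any source lists it with a qualifying
#' category; `intersection` mode requires all three sources.
#'
#' Matching is by upper-cased gene symbol so rat and human conventions
#' join.
#'
#' @param proteins Character vector of gene symbols, or a call tibble with
#'   a `gene_symbol` column.
#' @param catalog Tissue catalog tibble from [read_tissue_catalog()] or
#'   [generate_reference_resources()].
#' @param mode `"union"` (default) or `"intersection"`.
#' @return Tibble with columns `gene_symbol` (upper-cased, one row per
#'   distinct input symbol), `es` (logical) and `sources` (list column of
#'   matching source names).
#' @export
classify_es <- function(proteins, catalog, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.data.frame(proteins)) proteins <- proteins$gene_symbol
  symbols <- unique(toupper(proteins))
  catalog <- validate_tissue_catalog(catalog)
  if (nrow(catalog) == 0 && length(symbols) > 0) {
    warning("empty tissue catalog: no protein can be classified ES", call. = FALSE)
  }
  per_source <- split(toupper(catalog$gene_symbol), catalog$source)
  sources <- lapply(symbols, function(s) {
    hit <- names(per_source)[vapply(per_source, function(g) s %in% g, TRUE)]
    sort(hit)
  })
  n_required <- if (mode == "union") 1L else length(tissue_qualifying_categories())
  tibble::tibble(
    gene_symbol = symbols,
    es = vapply(sources, length, 0L) >= n_required,
    sources = sources
  )
}

#' @rdname classify_es
#' @param es Classification tibble from `classify_es()`.
#' @return `es_subset()`: the character vector of ES gene symbols.
#' @export
es_subset <- function(es) {
  es$gene_symbol[es$es]
}
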