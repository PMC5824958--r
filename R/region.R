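venn_cell_names <- function() {
  c("cc_only", "hp_only", "cb_only", "cc_hp", "cc_cb", "hp_cb", "all_three")
}

cell_region_sets <- function() {
  list(
    cc_only = "CC", hp_only = "HP", cb_only = "CB",
    cc_hp = c("CC", "HP"), cc_cb = c("CB", "CC"), hp_cb = c("CB", "HP"),
    all_three = c("CB", "CC", "HP")
  )
}

#' Seven-way Venn partition by brain-region membership
#'
#' Places every protein of a region-set assignment into exactly one of the
#' seven cells of the three-region Venn diagram (three exclusive, three
#' pairwise, one triple cell). Because the partition is computed from each
#' protein's region set, not from parallel per-region lists, cells are
#' disjoint by construction and their union is the full protein set.
#'
#' @param assignment Region-set assignment tibble (see
#'   [region_set_assignment()], [load_bri2_es_table()] or
#'   [calls_to_assignment()]).
#' @param id Column used to identify proteins in the cells; default
#'   `"gene_symbol"`.
#' @return Object of class `venn_partition7`: a named list of seven sorted
#'   character vectors (`cc_only`, `hp_only`, `cb_only`, `cc_hp`, `cc_cb`,
#'   `hp_cb`, `all_three`).
#' @export
venn_partition <- function(assignment, id = "gene_symbol") {
  stopifnot(id %in% names(assignment), "regions" %in% names(assignment))
  empty <- which(vapply(assignment$regions, length, 0L) == 0)
  if (length(empty) > 0) {
    stop_format("protein %s has an empty region set", assignment[[id]][empty[1]])
  }
  keys <- vapply(assignment$regions,
                 function(r) paste(sort(unique(r)), collapse = "+"), "")
  cells <- cell_region_sets()
  out <- lapply(cells, function(rs) {
    sort(assignment[[id]][keys == paste(rs, collapse = "+")])
  })
  structure(out, class = "venn_partition7")
}

#' @rdname venn_partition
#' @param partition A `venn_partition7`.
#' @return `venn_cell_sizes()`: named integer vector of the seven cell
#'   sizes.
#' @export
venn_cell_sizes <- function(partition) {
  vapply(partition, length, 0L)
}

#' @export
print.venn_partition7 <- function(x, ...) {
  sizes <- venn_cell_sizes(x)
  cat("7-way region Venn partition of", sum(sizes), "proteins\n")
  for (nm in names(sizes)) cat(sprintf("  %-9s %4d\n", nm, sizes[nm]))
  invisible(x)
}

#' Per-region totals from a Venn partition
#'
#' The total for region R is the sum of the four cells whose membership
#' pattern includes R (e.g. HP = hp_only + cc_hp + hp_cb + all_three).
#'
#' @param partition A `venn_partition7` (or a named vector/list of the
#'   seven cell sizes).
#' @return Named integer vector with elements `CC`, `HP`, `CB`.
#' @export
region_totals <- function(partition) {
  sizes <- if (inherits(partition, "venn_partition7")) {
    venn_cell_sizes(partition)
  } else {
    v <- vapply(partition, function(x) as.integer(x[[1]]), 0L)
    stopifnot(all(venn_cell_names() %in% names(v)))
    v[venn_cell_names()]
  }
  cells <- cell_region_sets()
  vapply(c(CC = "CC", HP = "HP", CB = "CB"), function(r) {
    sum(sizes[vapply(cells, function(rs) r %in% rs, TRUE)])
  }, 0L)
}

#' Overlap of calls with a reference interactor list
#'
#' Case-insensitive gene-symbol intersection; duplicate symbols in either
#' list count once after normalization.
#'
#' @param calls Character vector of symbols, or a tibble with a
#'   `gene_symbol` column.
#' @param reference Character vector of reference identifiers.
#' @return List with elements `overlap` (sorted upper-cased symbols) and
#'   `n` (its size).
#' @export
compare_to_reference <- function(calls, reference) {
  if (is.data.frame(calls)) calls <- calls$gene_symbol
  overlap <- sort(intersect(unique(toupper(calls)), unique(toupper(reference))))
  list(overlap = overlap, n = length(overlap))
}

#' @rdname venn_partition
#' @param path JSON output path.
#' @export
write_venn_json <- function(partition, path) {
  jsonlite::write_json(
    list(cells = lapply(unclass(partition), as.list),
         sizes = as.list(venn_cell_sizes(partition)),
         region_totals = as.list(region_totals(partition))),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
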