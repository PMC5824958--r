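#' Configuration for interactor calling
#'
#' Houses the decision rule applied per (region, replicate): a protein seen
#' in the bait co-IP is called an interactor either because it was never
#' seen in a mock control (`bait_only`) or because its bait:mock PSM ratio
#' reached `min_ratio` (`ratio_pass`).
#'
#' @param min_ratio Minimum bait/mock PSM ratio for a protein present in a
#'   mock to be kept; the boundary is inclusive ("equal or higher").
#'   Default 2.
#' @param mock_aggregation How the two mock counts combine into the ratio
#'   denominator when a protein appears in more than one mock: `"max"`
#'   (most conservative, default), `"sum"` or `"mean"`. A protein present
#'   in exactly one mock uses that mock's count.
#' @param min_replicate_support Number of replicates a protein must be
#'   called in to survive replicate merging. Default 1 (union semantics).
#' @return A `call_config` list.
#' @export
call_config <- function(min_ratio = 2,
                        mock_aggregation = c("max", "sum", "mean"),
                        min_replicate_support = 1L) {
  mock_aggregation <- match.arg(mock_aggregation)
  if (!is.numeric(min_ratio) || length(min_ratio) != 1 || min_ratio <= 0) {
    stop_format("min_ratio must be a single positive number")
  }
  if (!is.numeric(min_replicate_support) || length(min_replicate_support) != 1 ||
      min_replicate_support < 1 ||
      min_replicate_support != floor(min_replicate_support)) {
    stop_format("min_replicate_support must be a positive integer")
  }
  structure(
    list(min_ratio = min_ratio, mock_aggregation = mock_aggregation,
         min_replicate_support = as.integer(min_replicate_support)),
    class = "call_config"
  )
}

check_counts <- function(x, what) {
  if (length(x) == 0) return(invisible(x))
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    stop_format("%s must be non-negative integers", what)
  }
  invisible(x)
}

#' Call interactors from one replicate's bait and mock counts
#'
#' A protein is called iff it is present in the bait channel (count > 0)
#' and either (a) absent from both mocks (`bait_only`), or (b) present in
#' at least one mock with bait / agg(mock) >= `min_ratio` (`ratio_pass`).
#' Absence and a count of zero are equivalent; proteins absent from the
#' bait are never called.
#'
#' @param bait_counts Named non-negative integer vector, accession -> PSM.
#' @param mock_counts List of named count vectors, one per mock control.
#' @param config A [call_config()].
#' @return Tibble with columns `accession`, `evidence_class`
#'   (`"bait_only"` or `"ratio_pass"`) and `ratio` (`NA` for bait-only).
#' @export
call_replicate <- function(bait_counts, mock_counts, config = call_config()) {
  stopifnot(inherits(config, "call_config"), is.list(mock_counts))
  check_counts(bait_counts, "bait counts")
  for (m in mock_counts) check_counts(m, "mock counts")
  bait_counts <- bait_counts[bait_counts > 0]
  if (length(bait_counts) == 0) {
    return(tibble::tibble(accession = character(), evidence_class = character(),
                          ratio = numeric()))
  }
  agg <- switch(config$mock_aggregation, max = max, sum = sum, mean = mean)
  mock_for <- function(acc) {
    present <- unlist(lapply(mock_counts, function(m) {
      if (length(m) == 0 || !acc %in% names(m)) return(NULL)
      v <- m[[acc]]
      if (v == 0) NULL else v
    }))
    if (is.null(present)) 0 else agg(present)
  }
  denom <- vapply(names(bait_counts), mock_for, numeric(1))
  is_bait_only <- denom == 0
  ratio <- ifelse(is_bait_only, NA_real_, unname(bait_counts) / denom)
  keep <- is_bait_only | (!is.na(ratio) & ratio >= config$min_ratio)
  cls <- character(sum(keep))
  cls[unname(is_bait_only[keep])] <- "bait_only"
  cls[!unname(is_bait_only[keep])] <- "ratio_pass"
  tibble::tibble(
    accession = names(bait_counts)[keep],
    evidence_class = cls,
    ratio = unname(ratio[keep])
  )
}

#' Merge per-replicate calls into region-level interactor calls
#'
#' A protein is retained iff it was called in at least
#' `min_replicate_support` replicates. Its support set is recorded;
#' `max_ratio` is the maximum ratio across supporting replicates, and the
#' evidence class is `bait_only` only if the protein was bait-only in every
#' supporting replicate (mixed evidence resolves to the stronger
#' quantitative class, `ratio_pass`).
#'
#' @param replicate_calls Named list of per-replicate call tibbles from
#'   [call_replicate()]; names are replicate indices.
#' @param config A [call_config()].
#' @return Tibble with columns `accession`, `evidence_class`, `max_ratio`
#'   and `support` (list column of integer replicate indices).
#' @export
merge_replicates <- function(replicate_calls, config = call_config()) {
  stopifnot(length(replicate_calls) >= 1)
  if (config$min_replicate_support > length(replicate_calls)) {
    stop_format("min_replicate_support (%d) exceeds number of replicates (%d)",
                config$min_replicate_support, length(replicate_calls))
  }
  if (is.null(names(replicate_calls))) {
    names(replicate_calls) <- seq_along(replicate_calls)
  }
  stacked <- dplyr::bind_rows(replicate_calls, .id = "replicate")
  if (nrow(stacked) == 0) {
    return(tibble::tibble(accession = character(), evidence_class = character(),
                          max_ratio = numeric(), support = list()))
  }
  stacked$replicate <- as.integer(stacked$replicate)
  merged <- stacked |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      evidence_class = if (all(.data$evidence_class == "bait_only"))
        "bait_only" else "ratio_pass",
      max_ratio = if (all(is.na(.data$ratio))) NA_real_
        else max(.data$ratio, na.rm = TRUE),
      support = list(sort(unique(.data$replicate))),
      .groups = "drop"
    )
  merged[vapply(merged$support, length, 0L) >= config$min_replicate_support, ]
}

#' Call interactors per region from a full PSM table
#'
#' Splits the table by region and replicate, applies [call_replicate()]
#' with the bait channel against both mock channels, then merges
#' replicates with [merge_replicates()].
#'
#' @param psm PSM tibble as returned by [read_psm_table()].
#' @param config A [call_config()].
#' @return Tibble with columns `accession`, `gene_symbol`, `region`,
#'   `evidence_class`, `max_ratio`, `support`, sorted by region then
#'   accession.
#' @export
call_interactors <- function(psm, config = call_config()) {
  symbols <- psm |>
    dplyr::distinct(.data$accession, .data$gene_symbol)
  if (anyDuplicated(symbols$accession)) {
    stop_format("accession maps to more than one gene_symbol")
  }
  out <- lapply(intersect(coip_regions(), unique(psm$region)), function(reg) {
    sub <- psm[psm$region == reg, ]
    reps <- sort(unique(sub$replicate))
    rep_calls <- lapply(reps, function(r) {
      cell <- sub[sub$replicate == r, ]
      counts_of <- function(chan) {
        rows <- cell[cell$channel == chan, ]
        stats::setNames(rows$psm, rows$accession)
      }
      call_replicate(counts_of("bait"),
                     list(counts_of("mock_beads"), counts_of("mock_igg")),
                     config)
    })
    names(rep_calls) <- reps
    merged <- merge_replicates(rep_calls, config)
    merged$region <- rep(reg, nrow(merged))
    merged
  })
  dplyr::bind_rows(out) |>
    dplyr::left_join(symbols, by = "accession") |>
    dplyr::select("accession", "gene_symbol", "region", "evidence_class",
                  "max_ratio", "support") |>
    dplyr::arrange(.data$region, .data$accession)
}

#' Remove contaminant proteins from interactor calls
#'
#' Drops every call whose gene symbol or accession appears in the
#' contaminant list (case-insensitive) and reports how many were removed.
#'
#' @param calls Call tibble from [call_interactors()].
#' @param contaminants Character vector of identifiers (symbols and/or
#'   accessions); see [read_contaminants()] and [keratin_contaminants()].
#' @return The filtered call tibble, with attribute `n_removed`.
#' @export
filter_contaminants <- function(calls, contaminants) {
  bad <- toupper(contaminants)
  hit <- toupper(calls$gene_symbol) %in% bad | toupper(calls$accession) %in% bad
  if (any(hit)) {
    message(sprintf("filter_contaminants: removed %d contaminant call(s)", sum(hit)))
  }
  out <- calls[!hit, ]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Region-set assignment from interactor calls
#'
#' Collapses per-region calls into one row per protein with the set of
#' regions in which it was called — the object consumed by
#' [venn_partition()].
#'
#' @param calls Call tibble from [call_interactors()].
#' @return Tibble with `accession`, `gene_symbol` and a `regions` list
#'   column.
#' @export
calls_to_assignment <- function(calls) {
  collapsed <- calls |>
    dplyr::group_by(.data$accession, .data$gene_symbol) |>
    dplyr::summarise(regions = list(sort(unique(.data$region))), .groups = "drop")
  region_set_assignment(collapsed$accession, collapsed$gene_symbol,
                        collapsed$regions)
}

#' @rdname call_interactors
#' @param calls Call tibble.
#' @param path Output TSV path (support written as comma-separated list).
#' @export
write_calls <- function(calls, path) {
  flat <- calls
  flat$support <- vapply(calls$support, paste, "", collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname call_interactors
#' @export
read_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccccdc", progress = FALSE)
  x$support <- lapply(strsplit(x$support, ",", fixed = TRUE), as.integer)
  x
}
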