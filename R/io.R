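#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

#' Brain region and IP channel codes
#'
#' Region codes follow the three dissected rat brain regions (CC cerebral
#' cortex, HP hippocampus, CB cerebellum); channels distinguish the bait
#' co-IP from the two mock negative controls (beads only, beads + IgG).
#'
#' @return Character vector of allowed codes.
#' @export
coip_regions <- function() c("CC", "HP", "CB")

#' @rdname coip_regions
#' @export
coip_channels <- function() c("bait", "mock_beads", "mock_igg")

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Read a PSM count table
#'
#' Reads a tab-separated spectral-count table with one row per
#' (protein, region, channel, replicate) cell. Counts must be non-negative
#' integers; region and channel codes are validated against
#' [coip_regions()] and [coip_channels()]. A protein absent from a cell
#' simply has no row: absence and a zero count are treated identically
#' downstream.
#'
#' @param path Path to a TSV file with header columns `accession`,
#'   `gene_symbol`, `region`, `channel`, `replicate`, `psm`.
#' @return A tibble with those six columns (`replicate` and `psm` integer).
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop_format("PSM table not found: %s", path)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  required <- c("accession", "gene_symbol", "region", "channel", "replicate", "psm")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_format("PSM table %s is missing column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  x <- x[required]
  validate_psm_table(x, path)
}

validate_psm_table <- function(x, what = "PSM table") {
  psm_num <- suppressWarnings(as.numeric(x$psm))
  bad <- which(is.na(psm_num) | psm_num < 0 | psm_num != floor(psm_num))
  if (length(bad) > 0) {
    stop_format("%s: psm must be a non-negative integer (row %s, value '%s')",
                what, bad[1], x$psm[bad[1]])
  }
  bad_region <- which(!x$region %in% coip_regions())
  if (length(bad_region) > 0) {
    stop_format("%s: unknown region '%s' in row %s (allowed: %s)",
                what, x$region[bad_region[1]], bad_region[1],
                paste(coip_regions(), collapse = ", "))
  }
  bad_channel <- which(!x$channel %in% coip_channels())
  if (length(bad_channel) > 0) {
    stop_format("%s: unknown channel '%s' in row %s (allowed: %s)",
                what, x$channel[bad_channel[1]], bad_channel[1],
                paste(coip_channels(), collapse = ", "))
  }
  rep_num <- suppressWarnings(as.numeric(x$replicate))
  bad_rep <- which(is.na(rep_num) | rep_num < 1 | rep_num != floor(rep_num))
  if (length(bad_rep) > 0) {
    stop_format("%s: replicate must be a positive integer (row %s)", what, bad_rep[1])
  }
  out <- tibble::tibble(
    accession = x$accession,
    gene_symbol = x$gene_symbol,
    region = x$region,
    channel = x$channel,
    replicate = as.integer(rep_num),
    psm = as.integer(psm_num)
  )
  key <- paste(out$accession, out$region, out$channel, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop_format("%s: duplicate (accession, region, channel, replicate) at row %s",
                what, which(duplicated(key))[1])
  }
  out
}

#' @rdname read_psm_table
#' @param x A PSM tibble as returned by [read_psm_table()].
#' @export
write_psm_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a contaminant identifier list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers (verbatim case).
#' @export
read_contaminants <- function(path) {
  if (!file.exists(path)) stop_format("contaminant list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' The keratin contaminant list packaged with coipnet
#'
#' Fifteen keratins characteristic of hair, skin/epidermis, tongue and gums,
#' routinely excluded from co-IP interactor lists as handling contaminants.
#'
#' @return Character vector of 15 KRT gene symbols.
#' @export
keratin_contaminants <- function() {
  read_contaminants(system.file("extdata", "keratin_contaminants.txt",
                                package = "coipnet", mustWork = TRUE))
}

#' Load the packaged brain-enriched BRI2 interactome table
#'
#' A published reference table of 120 candidate BRI2 (ITM2B) interacting
#' proteins classified as highly enriched or specific for brain tissue,
#' with the rat brain regions (CC, HP, CB) in which each protein was
#' co-immunoprecipitated. Transcribed verbatim; protein names are carried
#' as metadata and never used in computation.
#'
#' @return A region-set assignment: tibble with columns `accession`,
#'   `gene_symbol`, `protein_name` and `regions` (list column of character
#'   vectors, each a non-empty subset of [coip_regions()]).
#' @export
load_bri2_es_table <- function() {
  path <- system.file("extdata", "bri2_es_interactome.tsv",
                      package = "coipnet", mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  stopifnot(identical(names(x), c("accession", "gene_symbol", "protein_name", "regions")))
  region_set_assignment(x$accession, x$gene_symbol,
                        strsplit(x$regions, ", ", fixed = TRUE),
                        protein_name = x$protein_name)
}

#' Construct a region-set assignment
#'
#' @param accession,gene_symbol Character vectors (parallel).
#' @param regions List of character vectors, each a non-empty subset of
#'   [coip_regions()].
#' @param protein_name Optional character vector of descriptive names.
#' @return A tibble with a `regions` list column, one row per protein.
#' @export
region_set_assignment <- function(accession, gene_symbol, regions,
                                  protein_name = NULL) {
  stopifnot(length(accession) == length(gene_symbol),
            length(accession) == length(regions))
  if (anyDuplicated(accession)) {
    stop_format("duplicate accession in region assignment: %s",
                accession[duplicated(accession)][1])
  }
  regions <- lapply(regions, function(r) sort(unique(as.character(r))))
  bad <- which(vapply(regions, function(r) {
    length(r) == 0 || !all(r %in% coip_regions())
  }, logical(1)))
  if (length(bad) > 0) {
    stop_format("protein %s has an empty or invalid region set", accession[bad[1]])
  }
  out <- tibble::tibble(accession = accession, gene_symbol = gene_symbol)
  if (!is.null(protein_name)) out$protein_name <- protein_name
  out$regions <- regions
  out
}

#' Read protein-protein interaction edges
#'
#' Supports two dialects: `edge_tsv` (columns `a`, `b`, `source`) and
#' `mitab25` (PSI-MITAB 2.5, of which only columns 1-2 are interpreted,
#' expected to carry `uniprotkb:`-prefixed identifiers; an optional
#' `source` column 3 is honoured for provenance). Identifiers are
#' normalized (database prefix stripped, symbols upper-cased), self-loops
#' are dropped with a warning, and duplicate unordered pairs are merged
#' keeping the union of their provenance tags.
#'
#' @param path Path to the edge file.
#' @param dialect One of `"edge_tsv"`, `"mitab25"`.
#' @return Tibble with columns `a`, `b` (normalized, `a` < `b`) and
#'   `sources` (list column of character provenance tags). An empty file
#'   yields a zero-row tibble.
#' @export
read_interactions <- function(path, dialect = c("edge_tsv", "mitab25")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("interaction file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (dialect == "edge_tsv" && length(lines) > 0 &&
      grepl("^a\tb", lines[1])) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    return(tibble::tibble(a = character(), b = character(), sources = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(f, i) {
    if (length(f) < 2) {
      stop_format("interaction file %s line %s: expected at least 2 columns", path, i)
    }
    a <- normalize_interactor_id(f[1], path, i)
    b <- normalize_interactor_id(f[2], path, i)
    src <- if (length(f) >= 3 && nzchar(f[3])) f[3] else dialect
    c(a = a, b = b, source = src)
  }
  parsed <- mapply(parse_one, fields, seq_along(fields), SIMPLIFY = FALSE)
  a <- vapply(parsed, `[[`, "", "a")
  b <- vapply(parsed, `[[`, "", "b")
  src <- vapply(parsed, `[[`, "", "source")
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop edge(s) in %s", sum(self), path),
            call. = FALSE)
    a <- a[!self]; b <- b[!self]; src <- src[!self]
  }
  merge_edges(tibble::tibble(a = a, b = b, sources = as.list(src)))
}

normalize_interactor_id <- function(id, path, line) {
  id <- trimws(id)
  # MITAB identifiers look like "uniprotkb:P31016"; keep the accession part.
  if (grepl(":", id, fixed = TRUE)) {
    id <- sub("^[A-Za-z0-9_-]+:", "", id)
  }
  if (!nzchar(id)) {
    stop_format("interaction file %s line %s: unparseable identifier", path, line)
  }
  toupper(id)
}

#' Merge duplicate unordered edge pairs
#'
#' Canonicalizes each edge so `a` < `b` and collapses duplicates, taking
#' the union of provenance tags. Idempotent.
#'
#' @param edges Tibble with columns `a`, `b`, `sources` (list column).
#' @return Merged edge tibble sorted by (`a`, `b`).
#' @export
merge_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  key <- paste(lo, hi, sep = "\r")
  groups <- split(seq_along(key), key)
  ord <- order(names(groups))
  groups <- groups[ord]
  tibble::tibble(
    a = unname(vapply(groups, function(i) lo[i[1]], "")),
    b = unname(vapply(groups, function(i) hi[i[1]], "")),
    sources = unname(lapply(groups, function(i) {
      sort(unique(unlist(edges$sources[i])))
    }))
  )
}

#' @rdname read_interactions
#' @param edges Edge tibble as returned by [read_interactions()].
#' @export
write_interactions <- function(edges, path) {
  flat <- tibble::tibble(
    a = edges$a, b = edges$b,
    source = vapply(edges$sources, paste, "", collapse = ";")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT annotation catalog
#'
#' Standard gene-set exchange format: one term per line,
#' `term_id TAB description TAB gene1 TAB gene2 ...`. Gene symbols are
#' upper-cased so rat (`Camk2a`) and human (`CAMK2A`) conventions join;
#' duplicate symbols within a set collapse.
#'
#' @param path Path to a GMT file.
#' @return Annotation catalog: tibble with columns `term_id`, `name` and
#'   `genes` (list column of unique upper-cased symbols).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3)
  if (length(short) > 0) {
    stop_format("GMT %s line %s: expected term, description and >= 1 gene",
                path, short[1])
  }
  term_id <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(term_id)) {
    stop_format("GMT %s: duplicate term_id '%s'", path,
                term_id[duplicated(term_id)][1])
  }
  tibble::tibble(
    term_id = term_id,
    name = vapply(fields, `[[`, "", 2),
    genes = lapply(fields, function(f) sort(unique(toupper(f[-(1:2)]))))
  )
}

#' @rdname read_gmt
#' @param catalog Annotation catalog tibble.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(c(catalog$term_id[i], catalog$name[i], catalog$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column identifier homology mapping
#'
#' Maps source identifiers (e.g. rat gene symbols) to target identifiers
#' (e.g. their human homologs). Many-to-one is allowed; a source mapped to
#' two distinct targets is an error.
#'
#' @param path Path to a headerless or headered two-column TSV
#'   (`source`, `target`).
#' @return Named character vector: `names()` are source identifiers,
#'   values the targets.
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) stop_format("id mapping not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) > 0 && grepl("^source\t", lines[1])) lines <- lines[-1]
  if (length(lines) == 0) return(stats::setNames(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2)
  if (length(bad) > 0) {
    stop_format("id mapping %s line %s: expected 2 columns", path, bad[1])
  }
  src <- vapply(fields, `[[`, "", 1)
  tgt <- vapply(fields, `[[`, "", 2)
  dup <- unique(src[duplicated(src)])
  for (d in dup) {
    if (length(unique(tgt[src == d])) > 1) {
      offenders <- paste(sprintf("%s -> %s", d, unique(tgt[src == d])),
                         collapse = "; ")
      stop_format("id mapping %s: ambiguous source '%s' (%s)", path, d, offenders)
    }
  }
  keep <- !duplicated(src)
  stats::setNames(tgt[keep], src[keep])
}

#' Read a brain tissue-expression catalog
#'
#' Three-source catalog of brain-enriched gene classifications; each row is
#' (source, gene_symbol, category). Sources and the categories that qualify
#' a gene as brain enriched/specific:
#' `hpa` ("Tissue enriched", "Tissue enhanced", "Group enriched"),
#' `tiger` ("brain-preferential"), `unigene` ("brain-restricted").
#'
#' @param path TSV with header `source`, `gene_symbol`, `category`.
#' @return Tibble with those columns, symbols upper-cased.
#' @export
read_tissue_catalog <- function(path) {
  if (!file.exists(path)) stop_format("tissue catalog not found: %s", path)
  x <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  required <- c("source", "gene_symbol", "category")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_format("tissue catalog %s missing column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  validate_tissue_catalog(tibble::tibble(
    source = x$source,
    gene_symbol = toupper(x$gene_symbol),
    category = x$category
  ))
}

tissue_qualifying_categories <- function() {
  list(
    hpa = c("Tissue enriched", "Tissue enhanced", "Group enriched"),
    tiger = "brain-preferential",
    unigene = "brain-restricted"
  )
}

validate_tissue_catalog <- function(x) {
  allowed <- tissue_qualifying_categories()
  bad_source <- which(!x$source %in% names(allowed))
  if (length(bad_source) > 0) {
    stop_format("tissue catalog: unknown source '%s' (allowed: %s)",
                x$source[bad_source[1]], paste(names(allowed), collapse = ", "))
  }
  for (s in names(allowed)) {
    rows <- x$source == s
    bad <- which(rows & !x$category %in% allowed[[s]])
    if (length(bad) > 0) {
      stop_format("tissue catalog: category '%s' not valid for source '%s'",
                  x$category[bad[1]], s)
    }
  }
  if (anyDuplicated(paste(x$source, x$gene_symbol, sep = "\r"))) {
    stop_format("tissue catalog: duplicate (source, gene_symbol) entry")
  }
  x
}

#' @rdname read_tissue_catalog
#' @param x Tissue catalog tibble.
#' @export
write_tissue_catalog <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
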