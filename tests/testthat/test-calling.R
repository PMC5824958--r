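test_that("per-replicate rule: ratio boundary, below-threshold, bait-only", {
  cfg <- call_config()
  # boundary: "equal or higher" keeps ratio exactly 2.0 (max aggregation)
  r <- call_replicate(c(A = 4), list(c(A = 2), c(A = 1)), cfg)
  expect_equal(r$evidence_class, "ratio_pass")
  expect_equal(r$ratio, 2.0)
  # below threshold, one mock absent
  r <- call_replicate(c(A = 3), list(c(A = 2), c()), cfg)
  expect_equal(nrow(r), 0)
  # never in the controls
  r <- call_replicate(c(A = 5), list(c(), c()), cfg)
  expect_equal(r$evidence_class, "bait_only")
  expect_true(is.na(r$ratio))
})

test_that("absence and zero counts are equivalent; absent-from-bait never called", {
  r0 <- call_replicate(c(A = 5), list(c(A = 0), c(A = 0)), call_config())
  expect_equal(r0$evidence_class, "bait_only")
  r1 <- call_replicate(c(A = 0, B = 4), list(c(B = 2), c()), call_config())
  expect_equal(r1$accession, "B")
  expect_error(call_replicate(c(A = -1), list(c(), c())), "non-negative")
  expect_error(call_replicate(c(A = 1.5), list(c(), c())), "non-negative")
})

test_that("mock aggregation modes change the denominator as configured", {
  bait <- c(A = 6)
  mocks <- list(c(A = 2), c(A = 4))
  ratio_of <- function(agg) {
    call_replicate(bait, mocks, call_config(mock_aggregation = agg))$ratio
  }
  expect_length(ratio_of("max"), 0)      # 6/4 = 1.5 < 2: not called
  expect_equal(ratio_of("mean"), 6 / 3)  # mean denominator 3 -> kept at 2.0
  expect_length(ratio_of("sum"), 0)      # 6/6 = 1 < 2: not called
})

test_that("call_replicate agrees with a literal brute-force rule on random instances", {
  set.seed(101)
  proteins <- sprintf("P%02d", 1:30)
  for (trial in 1:25) {
    bait <- random_counts(proteins)
    mocks <- list(random_counts(proteins), random_counts(proteins))
    agg <- sample(c("max", "sum", "mean"), 1)
    min_ratio <- sample(c(1.5, 2, 3), 1)
    got <- call_replicate(bait, mocks,
                          call_config(min_ratio = min_ratio, mock_aggregation = agg))
    want <- oracle_call_replicate(bait, mocks, min_ratio, agg)
    expect_setequal(got$accession, want$accession)
    expect_equal(
      got$evidence_class[order(got$accession)],
      want$evidence_class[order(want$accession)]
    )
  }
})

test_that("raising thresholds never adds a call (monotonicity)", {
  sim <- generate_experiment(tiny_sim_params(seed = 9))
  called_under <- function(min_ratio, support) {
    cfg <- call_config(min_ratio = min_ratio, min_replicate_support = support)
    unique(call_interactors(sim$psm, cfg)$accession)
  }
  base <- called_under(1.5, 1)
  for (mr in c(2, 3, 5)) {
    expect_true(all(called_under(mr, 1) %in% base))
  }
  sup1 <- called_under(2, 1)
  sup2 <- called_under(2, 2)
  sup3 <- called_under(2, 3)
  expect_true(all(sup2 %in% sup1))
  expect_true(all(sup3 %in% sup2))
})

test_that("replicate merging honours support thresholds and mixed evidence", {
  rep1 <- tibble::tibble(accession = "A", evidence_class = "ratio_pass", ratio = 3.0)
  rep2 <- tibble::tibble(accession = "A", evidence_class = "bait_only",
                         ratio = NA_real_)
  rep3 <- tibble::tibble(accession = character(), evidence_class = character(),
                         ratio = numeric())

  m1 <- merge_replicates(list(`1` = rep1, `2` = rep3, `3` = rep3), call_config())
  expect_equal(m1$support[[1]], 1L)

  m2 <- merge_replicates(list(`1` = rep1, `2` = rep3, `3` = rep3),
                         call_config(min_replicate_support = 2))
  expect_equal(nrow(m2), 0)

  # mixed evidence resolves to the stronger quantitative class
  m3 <- merge_replicates(list(`1` = rep1, `2` = rep2), call_config())
  expect_equal(m3$evidence_class, "ratio_pass")
  expect_equal(m3$max_ratio, 3.0)
  expect_equal(m3$support[[1]], c(1L, 2L))

  expect_error(
    merge_replicates(list(`1` = rep1), call_config(min_replicate_support = 2)),
    "exceeds"
  )
})

test_that("every planted bait-only protein is recalled and no call lacks bait evidence", {
  sim <- generate_experiment(tiny_sim_params(seed = 3))
  calls <- call_interactors(sim$psm)
  bait_accs <- unique(sim$psm$accession[sim$psm$channel == "bait"])
  expect_true(all(calls$accession %in% bait_accs))
  # bait-only planted proteins are absent from mocks in every region they
  # occupy, so the calling rule recalls them with certainty
  bo <- sim$truth$bait_only_interactors
  for (i in seq_len(nrow(bo))) {
    called_regions <- calls$region[calls$accession == bo$accession[i]]
    expect_setequal(called_regions, bo$regions[[i]])
  }
  # and planted truths are a subset of the calls
  expect_true(all(sim$truth$bait_only_interactors$accession %in% calls$accession))
})

test_that("contaminant filtering removes listed identifiers case-insensitively", {
  calls <- tibble::tibble(
    accession = c("P1", "P2", "P3"),
    gene_symbol = c("Krt5", "DLG4", "GAP43"),
    region = "CC", evidence_class = "bait_only",
    max_ratio = NA_real_, support = list(1L, 1L, 1L)
  )
  out <- suppressMessages(filter_contaminants(calls, keratin_contaminants()))
  expect_equal(out$gene_symbol, c("DLG4", "GAP43"))
  expect_equal(attr(out, "n_removed"), 1)
  # filtering by accession also works
  out2 <- suppressMessages(filter_contaminants(calls, c("p3")))
  expect_equal(out2$gene_symbol, c("Krt5", "DLG4"))
  # empty list is the identity
  out3 <- filter_contaminants(calls, character())
  expect_equal(out3$gene_symbol, calls$gene_symbol)
})

test_that("calls round-trip through write_calls/read_calls", {
  sim <- generate_experiment(tiny_sim_params(seed = 5))
  calls <- call_interactors(sim$psm)
  path <- tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path)
  expect_equal(back$accession, calls$accession)
  expect_equal(back$max_ratio, calls$max_ratio)
  expect_equal(back$support, calls$support)
})
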