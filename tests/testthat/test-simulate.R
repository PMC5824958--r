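test_that("the generator is deterministic under a fixed seed", {
  params <- tiny_sim_params(seed = 99)
  a <- generate_experiment(params)
  b <- generate_experiment(params)
  expect_identical(a$psm, b$psm)
  expect_identical(a$truth, b$truth)

  ra <- generate_reference_resources(params, a)
  rb <- generate_reference_resources(params, b)
  expect_identical(ra, rb)

  # emitted files are byte-identical across runs
  d1 <- file.path(tempfile(), "s1"); d2 <- file.path(tempfile(), "s2")
  p1 <- simulate_inputs(params, d1)
  p2 <- simulate_inputs(params, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]], warn = FALSE),
                     readLines(p2[[f]], warn = FALSE), label = f)
  }
  # and a different seed changes the draw
  c2 <- generate_experiment(tiny_sim_params(seed = 100))
  expect_false(identical(a$psm, c2$psm))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(planted_term_overlap = 50, planted_term_size = 30),
               "exceeds")
  expect_error(sim_params(bait_mean = 0), "positive")
  expect_error(sim_params(brain_enriched_fraction = 1.2), "0, 1")
  expect_error(sim_params(n_true_ratio = -1), "non-negative")
  expect_error(sim_params(regions = "CTX"), "subset")
})

test_that("every planted protein appears in the bait channel of its regions", {
  sim <- generate_experiment(tiny_sim_params(seed = 41))
  bait <- sim$psm[sim$psm$channel == "bait", ]
  planted <- dplyr::bind_rows(sim$truth$ratio_interactors,
                              sim$truth$bait_only_interactors)
  for (i in seq_len(nrow(planted))) {
    rows <- bait[bait$accession == planted$accession[i], ]
    # zero-truncated bait draws: present in every replicate of every
    # region the protein was planted in
    expect_setequal(unique(rows$region), planted$regions[[i]])
  }
  # bait-only proteins never occur in a mock channel
  mock <- sim$psm[sim$psm$channel != "bait", ]
  expect_length(intersect(mock$accession,
                          sim$truth$bait_only_interactors$accession), 0)
})

test_that("with no background or contaminants, calling recovers all planted truths", {
  params <- sim_params(n_true_ratio = 20, n_true_bait_only = 10,
                       n_background = 0, n_contaminants = 0, seed = 43)
  sim <- generate_experiment(params)
  calls <- call_interactors(sim$psm)
  expect_true(all(sim$truth$bait_only_interactors$accession %in% calls$accession))
  expect_true(all(calls$accession %in% unique(sim$psm$accession)))
})

test_that("planted-signal recovery at the calibrated effect size", {
  # ratio_effect 4, bait_mean 8, mock_mean 2: regression thresholds from
  # the package's own calibration of the default conditions
  params <- sim_params(seed = 47)
  sim <- generate_experiment(params)
  calls <- suppressMessages(
    filter_contaminants(call_interactors(sim$psm), sim$contaminants))
  planted <- c(sim$truth$ratio_interactors$accession,
               sim$truth$bait_only_interactors$accession)
  recall <- mean(planted %in% calls$accession)
  precision <- mean(calls$accession %in% planted)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.60)
})

test_that("bait counts have the configured mean when the effect is null", {
  params <- sim_params(n_true_ratio = 10000, n_true_bait_only = 0,
                       n_background = 0, n_contaminants = 0,
                       regions = "CC", replicates = 1,
                       ratio_effect = 1, bait_mean = 8, seed = 51)
  sim <- generate_experiment(params)
  bait <- sim$psm[sim$psm$channel == "bait", ]
  se <- sqrt(8 / nrow(bait))
  # zero-truncation shifts the mean by lambda * exp(-lambda)/(1-exp(-lambda)),
  # about 0.003 at lambda = 8 -- well inside the 3 SE band
  expect_lt(abs(mean(bait$psm) - 8), 3 * se + 0.01)
})

test_that("negative-binomial mode produces overdispersed counts", {
  params <- sim_params(n_true_ratio = 2000, n_true_bait_only = 0,
                       n_background = 0, n_contaminants = 0,
                       regions = "CC", replicates = 1, ratio_effect = 1,
                       bait_mean = 8, dispersion = 1, seed = 53)
  sim <- generate_experiment(params)
  bait <- sim$psm[sim$psm$channel == "bait", ]
  expect_gt(stats::var(bait$psm), 2 * mean(bait$psm))
})

test_that("contaminant leakage is zero after filtering with the generator's list", {
  sim <- generate_experiment(tiny_sim_params(seed = 59))
  calls <- call_interactors(sim$psm)
  filtered <- suppressMessages(filter_contaminants(calls, sim$contaminants))
  expect_length(intersect(filtered$gene_symbol, sim$truth$contaminants), 0)
})
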