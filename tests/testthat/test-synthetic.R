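test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_genomes = 1), "n_genomes")
  expect_error(sim_config(mutation_rate = 1.5), "mutation_rate")
  expect_error(sim_config(family_sd = -1), "family_sd")
  expect_error(sim_config(respiration_probs = c(weird_mode = 1)),
               "unknown respiration")
  expect_error(sim_config(prob_clamp = c(bnf = 2)), "prob_clamp")
  expect_error(sim_config(prob_clamp = c(not_a_strategy = 0.5)),
               "unknown strategy")
})

test_that("identical (config, seed) regenerate byte-identical outputs", {
  cfg <- sim_config(n_genomes = 6, seed = 99, decoys_per_genome = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_community(simulate_community(cfg), d1)
  write_community(simulate_community(cfg), d2)
  for (f in c("metadata.tsv", "truth.tsv",
              file.path("proteomes", "G00001.faa"),
              file.path("proteomes", "G00006.faa"))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the proteomes
  cfg2 <- sim_config(n_genomes = 6, seed = 100, decoys_per_genome = 5)
  d3 <- withr::local_tempdir()
  write_community(simulate_community(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "truth.tsv")),
                         readLines(file.path(d3, "truth.tsv"))))
})

test_that("probability clamps produce the degenerate worlds", {
  clamp1 <- stats::setNames(rep(1, 10), nstrat:::STRATEGIES)
  cfg <- sim_config(n_genomes = 4, seed = 5, prob_clamp = clamp1,
                    decoys_per_genome = 0)
  sim <- simulate_community(cfg)
  expect_true(all(as.matrix(sim$truth[, nstrat:::STRATEGIES]) == 1))
  # every genome carries at least the full required subunit complement:
  # 12 pathway markers + >= 1 transporter family
  for (g in sim$genomes) expect_gte(length(g$proteins), 13)

  clamp0 <- stats::setNames(rep(0, 10), nstrat:::STRATEGIES)
  cfg0 <- sim_config(n_genomes = 4, seed = 5, prob_clamp = clamp0,
                     decoys_per_genome = 50)
  sim0 <- simulate_community(cfg0)
  expect_true(all(as.matrix(sim0$truth[, nstrat:::STRATEGIES]) == 0))
  expect_true(all(vapply(sim0$genomes, function(g)
    length(g$proteins) == 50, logical(1))))
  # decoy-only proteomes yield zero strategies for every genome at
  # default thresholds
  profs <- test_profiles()
  thr <- test_thresholds()
  for (g in sim0$genomes) {
    h <- search_proteome(profs, g, thr)
    p <- call_strategies(h, genome_id = g$genome_id)
    expect_equal(strategy_count(p), 0)
  }
})

test_that("truth tables are rule-consistent and match planted proteins", {
  cfg <- sim_config(n_genomes = 30, seed = 17, decoys_per_genome = 0,
                    mutation_rate = 0)
  sim <- simulate_community(cfg)
  truth <- sim$truth
  # nitrate implies a nitrite route; amino-acid uptake implies a family
  expect_true(all(truth$nitrate_assim <=
                    pmax(truth$fd_nitrite, truth$nadh_nitrite)))
  fam_any <- apply(truth[, nstrat:::TRANSPORTER_FAMILIES], 1, max)
  expect_true(all(truth$amino_acid_uptake == fam_any))
  expect_equal(nrow(truth), cfg$n_genomes)
  # planted markers evaluate to the truth row under the rule engine
  for (i in seq_len(nrow(truth))) {
    markers <- sim$planted$marker_id[sim$planted$genome_id == truth$genome_id[i]]
    prof <- call_strategies(hits_from_markers(unique(markers),
                                              genome_id = truth$genome_id[i]),
                            genome_id = truth$genome_id[i])
    expect_identical(unname(prof$presence),
                     as.logical(truth[i, nstrat:::STRATEGIES]))
  }
})

test_that("pipeline round-trip: noiseless planted communities reproduce truth", {
  profs <- test_profiles()
  thr <- test_thresholds()
  cfg <- sim_config(n_genomes = 10, seed = 23, mutation_rate = 0,
                    decoys_per_genome = 0)
  sim <- simulate_community(cfg, profiles = profs)
  for (i in seq_along(sim$genomes)) {
    h <- search_proteome(profs, sim$genomes[[i]], thr)
    p <- call_strategies(h, genome_id = sim$genomes[[i]]$genome_id)
    expect_identical(unname(p$presence),
                     as.logical(sim$truth[i, nstrat:::STRATEGIES]))
    expect_identical(unname(p$transporter_families),
                     as.logical(sim$truth[i, nstrat:::TRANSPORTER_FAMILIES]))
  }
})

test_that("metadata links CDS count to genome length deterministically", {
  cfg <- sim_config(n_genomes = 20, seed = 3)
  sim <- simulate_community(cfg, emit_proteins = FALSE)
  md <- sim$metadata
  expect_equal(md$n_cds, round(md$genome_length_bp / 1000))
  expect_true(all(md$respiration_mode %in% nstrat:::RESPIRATION_MODES))
  expect_true(all(md$host_associated %in% c(0, 1)))
  expect_true(all(md$completeness > 90 & md$contamination < 5))
  # covariate/truth draws are identical with and without protein emission
  sim2 <- simulate_community(cfg, emit_proteins = TRUE)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$metadata, sim2$metadata)
})

test_that("count scaling on truth recovers the model-implied slope", {
  # single nonzero effect: beta_size = 2 per log10 bp, shared across
  # strategies.  The implied OLS slope of count on log10 length is the
  # generative derivative  sum_s beta * p_s(x) (1 - p_s(x))  averaged
  # over the sampled covariate range (Monte-Carlo oracle, computed from
  # the model before fitting).
  beta <- 2.0
  zero_resp <- lapply(nstrat:::RESPIRATION_MODES, function(m)
    stats::setNames(rep(0, 10), nstrat:::STRATEGIES))
  names(zero_resp) <- nstrat:::RESPIRATION_MODES
  cfg <- sim_config(n_genomes = 500, seed = 31, beta_size = beta,
                    beta_respiration = zero_resp,
                    beta_host = stats::setNames(rep(0, 10), nstrat:::STRATEGIES),
                    family_sd = 0)
  base <- cfg$baseline_logit
  xs <- seq(cfg$log10_length_range[1], cfg$log10_length_range[2],
            length.out = 2001)
  expected_count <- vapply(xs, function(x) {
    p <- stats::plogis(base + beta * (x - cfg$ref_log10_length))
    # nitrate without a nitrite route forces the ferredoxin route
    sum(p) + p[["nitrate_assim"]] * (1 - p[["fd_nitrite"]]) *
      (1 - p[["nadh_nitrite"]])
  }, numeric(1))
  # population least-squares slope of E[count | x] on x over uniform x
  implied_slope <- stats::cov(xs, expected_count) / stats::var(xs)
  sim <- simulate_community(cfg, emit_proteins = FALSE)
  counts <- rowSums(sim$truth[, nstrat:::STRATEGIES])
  fit <- fit_count_scaling(counts, sim$metadata$genome_length_bp)
  slope <- fit$statistics$slope
  se <- fit$coefficients$se[fit$coefficients$term == "log10_length"]
  expect_lt(abs(slope - implied_slope), 2 * se)
})
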