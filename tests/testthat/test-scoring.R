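test_that("M=1 background-emission profile scores 0 on one residue", {
  msa <- nstrat:::new_msa(c("a", "b"), c("A", "A"))
  p <- build_profile(msa, pseudocount = 1e12)  # emissions -> background
  for (res in c("A", "C", "W")) {
    expect_equal(score_sequence(p, res), 0, tolerance = 1e-6)
  }
})

test_that("forward score equals exhaustive path enumeration (M<=3, len<=4)", {
  set.seed(7)
  aa <- nstrat:::AA_ALPHABET
  n_cases <- 0
  for (M in 1:3) {
    for (rep in 1:25) {
      prof <- random_profile(M, seed = M * 1000 + rep)
      for (L in 1:4) {
        s <- paste(sample(aa, L, replace = TRUE), collapse = "")
        expect_equal(score_sequence(prof, s), enum_forward_bits(prof, s),
                     tolerance = 1e-9)
        n_cases <- n_cases + 1
      }
    }
  }
  expect_gte(n_cases, 200)
})

test_that("wildcard residues score as background", {
  prof <- random_profile(3, seed = 99)
  expect_equal(score_sequence(prof, "AXC"), enum_forward_bits(prof, "AXC"),
               tolerance = 1e-9)
})

test_that("scorer validates its input", {
  prof <- random_profile(2, seed = 1)
  expect_error(score_sequence(prof, ""), "non-empty")
  expect_error(score_sequence(prof, "A1C"), "illegal")
})

test_that("planted sequences separate from background decoys", {
  profs <- test_profiles()
  p <- profs$AmtB
  set.seed(11)
  planted <- nstrat:::emit_from_profile(p)
  planted_score <- score_sequence(p, planted)
  decoy_scores <- vapply(1:100, function(i)
    score_sequence(p, nstrat:::emit_background(nchar(planted))), numeric(1))
  expect_true(planted_score > max(decoy_scores))
})

test_that("null calibration recovers known Gumbel parameters", {
  # method-of-moments on synthetic Gumbel(mu = 0, lambda = 1) scores
  set.seed(123)
  x <- -log(-log(runif(10000)))  # standard Gumbel draws
  lambda_hat <- pi / (sd(x) * sqrt(6))
  mu_hat <- mean(x) - 0.5772156649015329 / lambda_hat
  expect_lt(abs(mu_hat - 0), 0.05)
  expect_lt(abs(lambda_hat - 1), 0.05)
})

test_that("calibrate_null fits scores and evalue matches the closed form", {
  profs <- test_profiles()
  cal <- calibrate_null(profs$NifH, n_samples = 150, seed = 3)
  expect_gt(cal$gumbel_lambda, 0)
  # E-value at score = mu with one target is exp(Euler-Mascheroni) ~ 1.78?
  # No: E(mu) = 1 * exp(-lambda * 0) = 1 by the stated formula.
  expect_equal(evalue(cal, cal$gumbel_mu, n_targets = 1), 1)
  # at one Euler-Mascheroni unit below mu: exp(0.5772...) ~ 1.781
  s <- cal$gumbel_mu - 0.5772156649015329 / cal$gumbel_lambda
  expect_equal(evalue(cal, s, n_targets = 1), exp(0.5772156649015329),
               tolerance = 1e-9)
  expect_error(calibrate_null(profs$NifH, n_samples = 50), ">= 100")
})

test_that("calibration errors on zero score variance", {
  prof <- random_profile(1, seed = 5)
  # constant-length decoys against an M=1 profile with background-equal
  # emissions give constant scores
  prof$match_emis[1, ] <- prof$background
  prof$insert_emis <- prof$background
  expect_error(calibrate_null(prof, n_samples = 100, lengths = 50, seed = 1),
               "zero score variance")
})

test_that("proteome search is specific, sensitive and deterministic", {
  profs <- test_profiles()
  thr <- test_thresholds()
  # decoy-only proteome: no hits at default thresholds
  set.seed(21)
  decoys <- vapply(1:50, function(i) nstrat:::emit_background(80), character(1))
  g <- genome_record("Gdecoy", decoys)
  expect_equal(nrow(search_proteome(profs, g, thr)), 0)
  # exact NifH consensus: a NifH hit, no NifD/NifK hits
  g2 <- genome_record("Gcons", c(nifh = consensus_sequence(profs$NifH)))
  h <- search_proteome(profs, g2, thr)
  expect_true("NifH" %in% h$marker_id)
  expect_false(any(c("NifD", "NifK") %in% h$marker_id))
  # determinism
  expect_identical(h, search_proteome(profs, g2, thr))
  # missing threshold is an error
  expect_error(search_proteome(profs, g2, thr[-1]), "no bit threshold")
})

test_that("hits are sorted by marker, descending score, protein id", {
  profs <- test_profiles()[c("AmtB", "UreC")]
  thr <- test_thresholds()[c("AmtB", "UreC")]
  set.seed(31)
  prot <- c(b_amtb = nstrat:::emit_from_profile(profs$AmtB),
            a_amtb = nstrat:::emit_from_profile(profs$AmtB),
            z_urec = nstrat:::emit_from_profile(profs$UreC))
  h <- search_proteome(profs, genome_record("G1", prot), thr)
  expect_equal(h$marker_id, sort(h$marker_id))
  amtb <- h[h$marker_id == "AmtB", ]
  expect_true(all(diff(amtb$bit_score) <= 0))
})

test_that("specificity: decoy false-positive rate <= 1% per marker", {
  profs <- test_profiles()
  thr <- test_thresholds()
  set.seed(77)
  n_decoys <- 1000
  lens <- sample(40:150, n_decoys, replace = TRUE)
  decoys <- vapply(lens, nstrat:::emit_background, character(1))
  for (mid in c("AmtB", "NifH", "Chitinase", "APC")) {
    scores <- vapply(decoys, function(s) score_sequence(profs[[mid]], s),
                     numeric(1))
    fp <- mean(scores >= thr[[mid]])
    expect_lte(fp, 0.01)
  }
})

test_that("sensitivity: noiseless recovery 1.0, rate >= 0.9 at 10% mutation", {
  profs <- test_profiles()
  thr <- test_thresholds()
  set.seed(55)
  for (mid in c("AmtB", "NifH", "BCCT")) {
    clean <- vapply(1:50, function(i)
      nstrat:::emit_from_profile(profs[[mid]], n_inserts = rpois(1, 2)),
      character(1))
    rate_clean <- mean(vapply(clean, function(s)
      score_sequence(profs[[mid]], s) >= thr[[mid]], logical(1)))
    expect_equal(rate_clean, 1.0)
    noisy <- vapply(1:50, function(i)
      nstrat:::emit_from_profile(profs[[mid]], n_inserts = rpois(1, 2),
                                 mutation_rate = 0.1), character(1))
    rate_noisy <- mean(vapply(noisy, function(s)
      score_sequence(profs[[mid]], s) >= thr[[mid]], logical(1)))
    expect_gte(rate_noisy, 0.9)
  }
})

test_that("tblout parsing: comments, echo, round-trip, malformed rows", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# comment", "# another"), f)
  expect_equal(nrow(read_hmmer_tblout(f)), 0)

  writeLines(c("# hdr",
               paste("G1|p1 - NifH - 1e-10 55.2 0.1 1e-10 55.0 0.1",
                     "1.0 1 0 0 1 1 1 1 -")), f)
  h <- read_hmmer_tblout(f)
  expect_equal(nrow(h), 1)
  expect_equal(h$bit_score, 55.2)
  expect_equal(h$e_value, 1e-10)
  expect_equal(h$genome_id, "G1")
  expect_equal(h$protein_id, "p1")
  expect_equal(h$marker_id, "NifH")
  expect_true(h$known_marker)

  writeLines("G1|p1 - NifH - 1e-10 55.2", f)
  expect_error(read_hmmer_tblout(f), "line 1")

  # 20 synthetic hits round-trip
  set.seed(9)
  hits <- data.frame(genome_id = sprintf("G%02d", 1:20),
                     protein_id = sprintf("p%02d", 1:20),
                     marker_id = sample(nstrat:::MARKER_IDS, 20, replace = TRUE),
                     bit_score = round(runif(20, 20, 300), 4),
                     e_value = 10^-runif(20, 3, 30),
                     source = "native", stringsAsFactors = FALSE)
  write_hmmer_tblout(hits, f)
  back <- read_hmmer_tblout(f)
  expect_equal(back$genome_id, hits$genome_id)
  expect_equal(back$protein_id, hits$protein_id)
  expect_equal(back$marker_id, hits$marker_id)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-6)
  expect_equal(back$e_value, hits$e_value, tolerance = 1e-6)
})

test_that("hits TSV round-trips through the pinned dialect", {
  hits <- data.frame(genome_id = "G1", protein_id = "p1", marker_id = "AmtB",
                     bit_score = 123.456789, e_value = 3.2e-12,
                     source = "native", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  back <- read_hits(f)
  expect_equal(back$bit_score, 123.456789, tolerance = 1e-6)
  expect_equal(back$e_value, 3.2e-12, tolerance = 1e-6)
})
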