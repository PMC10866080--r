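test_that("count scaling: perfect linear data gives R^2 = 1, exact slope", {
  lens <- 10^seq(6, 7, length.out = 50)
  counts <- 2 + 3 * log10(lens)
  # summary.lm warns on an essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_count_scaling(counts, lens))
  expect_equal(fit$statistics$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$statistics$slope, 3, tolerance = 1e-9)
  expect_error(fit_count_scaling(c(1, 2), c(10, 20)), ">= 3")
  expect_error(fit_count_scaling(1:5, rep(1e6, 5)), "zero variance")
})

test_that("count scaling: type-I error is nominal under the null", {
  rejections <- vapply(1:200, function(s) {
    set.seed(s)
    lens <- 10^runif(500, 6, 7)
    counts <- rpois(500, 4)  # independent of length
    fit_count_scaling(counts, lens)$statistics$slope_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("group_compare: balanced ranks give H = 0; exact small-sample W", {
  res <- group_compare(c(1, 4, 2, 3), c("a", "a", "b", "b"))
  expect_equal(res$statistics$kw_statistic, 0, tolerance = 1e-12)
  # fully separated samples: W at its extreme; exact p from the 20
  # arrangements of ranks is 2/20 = 0.1 (two-sided)
  res2 <- group_compare(c(1, 2, 3, 10, 11, 12),
                        rep(c("lo", "hi"), each = 3))
  pw <- res2$coefficients
  expect_equal(pw$w_statistic, 9)  # hi vs lo: all 9 pairwise wins
  expect_equal(pw$p_value, 0.1)
  expect_equal(pw$direction, 1)    # group_a = "hi" has the larger median
})

test_that("group_compare pairwise p-values match exhaustive permutation", {
  # exact two-sided rank-sum p by enumerating all assignments
  exact_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    combs <- utils::combn(length(pooled), n)
    w_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    ws <- apply(combs, 2, function(idx)
      sum(rank(pooled)[idx]) - n * (n + 1) / 2)
    mean_w <- n * (length(y)) / 2
    mean(abs(ws - mean_w) >= abs(w_obs - mean_w) - 1e-9)
  }
  set.seed(33)
  for (rep in 1:10) {
    x <- sample(1:100, 4)
    y <- sample(101:200, 5) / 7  # distinct values, no ties
    res <- group_compare(c(x, y), rep(c("x", "y"), c(4, 5)))
    expect_equal(res$coefficients$p_value, exact_p(x, y), tolerance = 1e-9)
  }
})

test_that("group_compare null rejection rate is nominal", {
  rejections <- vapply(1:200, function(s) {
    set.seed(s + 900)
    vals <- rnorm(90)
    groups <- sample(rep(c("a", "b", "c"), each = 30))
    group_compare(vals, groups)$statistics$kw_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.04)
})

test_that("group_compare excludes tiny groups with a warning", {
  expect_warning(res <- group_compare(c(1, 2, 3, 4, 9),
                                      c("a", "a", "b", "b", "c")),
                 "excluding")
  expect_equal(sort(names(res$grouping)), c("a", "b"))
  expect_error(suppressWarnings(group_compare(c(1, 2, 3), c("a", "a", "b"))),
               ">= 2 groups")
})

test_that("presence model recovers null and planted respiration effects", {
  # null: aerobic coefficient within 2 SE of zero in >= 95% of seeds
  ok_null <- vapply(1:20, function(s) {
    set.seed(s + 50)
    mode <- sample(c("aerobic", "anaerobic"), 1000, replace = TRUE)
    y <- rbinom(1000, 1, 0.3)
    fit <- fit_presence_model(y, mode)
    co <- fit$coefficients[fit$coefficients$term == "modeaerobic", ]
    abs(co$estimate) <= 2 * co$se
  }, logical(1))
  expect_gte(mean(ok_null), 0.95)
  # degenerate outcome errors
  expect_error(fit_presence_model(rep(1, 10), rep(c("aerobic", "anaerobic"), 5)),
               "degenerate")
})

test_that("presence model reports separation instead of failing silently", {
  mode <- rep(c("aerobic", "anaerobic"), each = 20)
  y <- as.integer(mode == "aerobic")  # complete separation
  fit <- fit_presence_model(y, mode)
  expect_false(fit$statistics$converged)
  expect_match(fit$statistics$diagnostic, "separation")
})

test_that("family adjustment accepts fixed and random forms", {
  set.seed(61)
  n <- 400
  mode <- sample(c("aerobic", "anaerobic"), n, replace = TRUE)
  fam <- sample(sprintf("f%02d", 1:10), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 1 * (mode == "aerobic")))
  fixed <- fit_presence_model(y, mode, family_ids = fam,
                              model = "logistic_with_family")
  expect_true(any(grepl("^fam", fixed$coefficients$term)))
  rand <- fit_presence_model(y, mode, family_ids = fam,
                             model = "logistic_with_family",
                             family_random = TRUE)
  co <- rand$coefficients[rand$coefficients$term == "modeaerobic", ]
  expect_gt(co$estimate, 0)
  expect_error(fit_presence_model(y, mode, model = "logistic_with_family"),
               "family_ids")
})

test_that("Poisson habitat model recovers a doubled rate as log 2", {
  set.seed(71)
  n <- 1000
  eco <- sample(c("soil", "marine"), n, replace = TRUE, prob = c(0.7, 0.3))
  lam <- ifelse(eco == "marine", 2, 1)
  y <- rpois(n, lam)
  fit <- fit_habitat_counts(y, eco)
  co <- fit$coefficients[fit$coefficients$term == "ecomarine", ]
  expect_lt(abs(co$estimate - log(2)), 2 * co$se)
  expect_equal(fit$statistics$reference, "soil")  # largest category
  expect_error(fit_habitat_counts(y, rep("soil", n)), ">= 2 ecosystems")
  expect_error(fit_habitat_counts(-y, eco), ">= 0")
})

test_that("Poisson habitat model: null coefficients near zero", {
  ok <- vapply(1:20, function(s) {
    set.seed(s + 700)
    eco <- sample(c("soil", "marine", "host"), 1000, replace = TRUE)
    y <- rpois(1000, 2)
    fit <- fit_habitat_counts(y, eco)
    co <- fit$coefficients[grepl("^eco", fit$coefficients$term), ]
    all(abs(co$estimate) <= 2 * co$se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("habitat model flags all-zero ecosystems as unstable", {
  eco <- rep(c("soil", "vacuum"), each = 30)
  y <- c(rpois(30, 2), rep(0, 30))
  fit <- fit_habitat_counts(y, eco)
  co <- fit$coefficients
  expect_true(co$unstable[co$term == "ecovacuum"])
})

test_that("host contrast is the Welch form with closed-form arithmetic", {
  # identical groups: t = 0, p = 1
  res <- host_contrast(c(1, 2, 3, 1, 2, 3), c(F, F, F, T, T, T))
  expect_equal(res$statistics$t, 0)
  expect_equal(res$statistics$p, 1)
  # {0,0,0,0} vs {1,1,1,1} with tiny jitter: |t| huge, Welch df = 6
  # (equal jitter variances make Welch-Satterthwaite exact at 2(n-1))
  jit <- c(0, 1, 2, 3) * 1e-9
  a <- 0 + jit; b <- 1 + jit
  res2 <- host_contrast(c(a, b), c(rep(FALSE, 4), rep(TRUE, 4)))
  expect_gt(abs(res2$statistics$t), 1e6)
  # hand-computed Welch-Satterthwaite df
  va <- var(a) / 4; vb <- var(b) / 4
  df_hand <- (va + vb)^2 / (va^2 / 3 + vb^2 / 3)
  expect_equal(res2$statistics$df, df_hand, tolerance = 1e-6)
  expect_equal(res2$statistics$df, 6, tolerance = 1e-3)
  # degenerate inputs
  expect_error(host_contrast(c(1, 1, 1, 1), c(F, F, T, T)), "undefined")
  expect_error(host_contrast(c(1, 2, 3), c(F, F, T)), ">= 2 members")
})

test_that("planted effect directions are recovered on synthetic data", {
  # host depletion of inorganic strategies: free-living mean inorganic
  # fraction exceeds host-associated mean (single-scenario check; the
  # 20-seed acceptance suite covers the full contract)
  cfg <- sim_config(n_genomes = 600, seed = 5)
  sim <- simulate_community(cfg, emit_proteins = FALSE)
  tr <- sim$truth
  counts <- rowSums(tr[, nstrat:::STRATEGIES])
  inorg <- rowSums(tr[, nstrat:::INORGANIC_STRATEGIES])
  keep <- counts > 0
  res <- host_contrast((inorg / counts)[keep],
                       sim$metadata$host_associated[keep] == 1)
  expect_gt(res$statistics$mean_free_living,
            res$statistics$mean_host_associated)
})
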