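test_that("moderated statistic matches hand values and direct recomputation", {
  expect_equal(moderated_statistic(c(0, 0, 0), 0.6), 0)
  expect_equal(moderated_statistic(c(1, 1, 1), 0.6), 1 / 0.6)
  x <- c(0.8, 1.2, 1.0)
  expect_equal(moderated_statistic(x, 0.6),
               mean(x) / (sd(x) / sqrt(3) + 0.6), tolerance = 1e-12)
  expect_error(moderated_statistic(c(1, NA)), "insufficient replication")
})

test_that("moderated statistic is antisymmetric and vanishes as s0 grows", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1))
    expect_equal(moderated_statistic(-x, 0.6), -moderated_statistic(x, 0.6),
                 tolerance = 1e-12)
    expect_lt(abs(moderated_statistic(x, 1e6)), 1e-5)
  }
})

test_that("a null site is its own null", {
  tab <- make_site_table(1, ratios = list(e1_HL_r1 = 1, e1_HL_r2 = 1,
                                          e1_HL_r3 = 1))
  res <- permutation_fdr(tab, regulation_config())
  expect_equal(res$q_value, 1)
  expect_equal(res$d, 0)
})

test_that("sampled q-values equal the full sign-flip enumeration at n=3", {
  set.seed(12)
  n <- 50
  l2 <- matrix(rnorm(n * 3, 0, 0.5), ncol = 3)
  l2[1:8, ] <- l2[1:8, ] + 2
  tab <- make_site_table(n, ratios = list(e1_HL_r1 = 2^l2[, 1],
                                          e1_HL_r2 = 2^l2[, 2],
                                          e1_HL_r3 = 2^l2[, 3]))
  res <- permutation_fdr(tab, regulation_config(n_permutations = 500))
  X <- log2(as.matrix(as.data.frame(tab)[sapply(1:3, function(r)
    ratio_column(1, "H/L", r))]))
  expect_equal(res$q_value, oracle_exhaustive_q(X, 0.6), tolerance = 1e-12)
})

test_that("q-values are monotone in |d|, bounded and seed-deterministic", {
  sim <- simulate_phosphoproteome(simulation_config(
    n_sites = 300, n_ikk_substrates = 10, n_tnf_responders = 40,
    n_replicates = 5, missing_rate = 0, seed = 13))
  cfg <- regulation_config(n_permutations = 20, seed = 99)
  res <- permutation_fdr(sim$sites, cfg)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  ord <- order(-abs(res$d))
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  res2 <- permutation_fdr(sim$sites, cfg)
  expect_identical(res, res2)
})

test_that("sites with too few replicates are skipped with a reason", {
  tab <- make_site_table(3, ratios = list(e1_HL_r1 = c(2, 2, NA),
                                          e1_HL_r2 = c(4, NA, NA),
                                          e1_HL_r3 = c(3, NA, 2)))
  res <- permutation_fdr(tab, regulation_config())
  expect_equal(res$site_id, "s001")
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$site_id, c("s002", "s003"))
  expect_match(skipped$reason[1], "finite replicate")
})

test_that("regulated calls require both the FDR and the fold-change gate", {
  res <- data.frame(site_id = c("a", "b", "c", "d"),
                    n_obs = 3, d = c(3, 3, -3, 0.1),
                    mean_log2_fc = log2(c(1.6, 1.4, 1 / 1.6, 1.01)),
                    fold_change = c(1.6, 1.4, 1 / 1.6, 1.01),
                    q_value = c(0.01, 0.001, 0.01, 0.9))
  out <- call_regulated(res, regulation_config())
  expect_equal(out$regulated, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("up", "up", "down", "up"))
  expect_identical(out, call_regulated(res, regulation_config()))
})

test_that("inhibition fractions follow the log2-excess formula", {
  reg <- data.frame(site_id = c("s001", "s002", "s003"),
                    n_obs = 3, d = 3, mean_log2_fc = 2, fold_change = 4,
                    q_value = 0.001, direction = "up", regulated = TRUE)
  merged <- make_site_table(3, ratios = list(
    e2_ML_r1 = 2^c(3.32, 2, 2),
    e2_HL_r1 = 2^c(0.2, 2, NA)))
  merged <- merge_replicates(merged)$table
  out <- inhibition_set(reg, merged, regulation_config())
  expect_equal(out$inhibition[1], 1 - 0.2 / 3.32, tolerance = 1e-12)
  expect_true(out$retained[1])                # 94% inhibition
  expect_equal(out$inhibition[2], 0)          # excess unchanged
  expect_false(out$retained[2])
  expect_false(out$retained[3])               # missing inhibitor arm
  excl <- attr(out, "excluded")
  expect_equal(excl$site_id, "s003")
  expect_match(excl$reason, "missing")
})

test_that("raw-ratio inhibition scale is available behind the config switch", {
  reg <- data.frame(site_id = "s001", n_obs = 3, d = 3, mean_log2_fc = 2,
                    fold_change = 4, q_value = 0.001, direction = "up",
                    regulated = TRUE)
  merged <- merge_replicates(make_site_table(1, ratios = list(
    e2_ML_r1 = 10, e2_HL_r1 = 1.5)))$table
  out <- inhibition_set(reg, merged,
                        regulation_config(inhibition_scale = "ratio"))
  expect_equal(out$inhibition, 1 - 0.5 / 9, tolerance = 1e-12)
})

test_that("knockdown recovery: the inhibited set approximates the substrate set", {
  sim <- simulate_phosphoproteome(simulation_config(
    n_sites = 800, n_ikk_substrates = 60, n_tnf_responders = 60,
    n_replicates = 3, inhibitor_knockdown_frac = 0.95, missing_rate = 0,
    noise_sd_log2 = 0.1, seed = 14))
  cfg <- regulation_config()
  reg <- call_regulated(permutation_fdr(sim$sites, cfg), cfg)
  merged <- merge_replicates(sim$sites)$table
  inhib <- inhibition_set(reg, merged, cfg)
  retained <- inhib$site_id[inhib$retained]
  substrates <- sim$truth$site_id[sim$truth$class == "IKK_SUBSTRATE"]
  jaccard <- length(intersect(retained, substrates)) /
    length(union(retained, substrates))
  expect_gte(jaccard, 0.8)
})

test_that("overlap fraction matches set arithmetic and sampling expectation", {
  expect_equal(overlap_fraction(c("1", "2", "3", "4"), c("1", "2", "3")), 0.75)
  expect_equal(overlap_fraction(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b")), 1)
  expect_error(overlap_fraction(character(0), "a"), "empty")

  set.seed(15)
  universe <- sprintf("u%03d", 1:100)
  fracs <- vapply(1:500, function(i) {
    overlap_fraction(sample(universe, 80), sample(universe, 60))
  }, numeric(1))
  # E|a intersect b|/|a| = 60/100 under uniform sampling
  se <- sd(fracs) / sqrt(500)
  expect_lt(abs(mean(fracs) - 0.6), 3 * se)
})
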