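# Small feature matrix with a planted informative feature, bypassing the
# simulation pipeline.
toy_feature_matrix <- function(n_pos = 10, n_neg = 200, shift = 2, seed = 41,
                               incomplete = 0) {
  set.seed(seed)
  n <- n_pos + n_neg
  fm <- data.frame(site_id = sprintf("t%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (col in phosphoscreen:::BASE_FEATURES) fm[[col]] <- rnorm(n)
  fm$l2r_e1_HL <- fm$l2r_e1_HL + c(rep(shift, n_pos), rep(0, n_neg))
  fm$kinase_basal <- rnorm(n)
  fm$wt_vs_kd_tnf <- rnorm(n) + c(rep(shift, n_pos), rep(0, n_neg))
  fm$kd_vs_tnf <- rnorm(n)
  for (p in sprintf("p%02d", 1:31)) {
    fm[[paste0("seq_ikk_", p)]] <- rnorm(n)
    fm[[paste0("seq_tnf_", p)]] <- rnorm(n)
  }
  fm$complete_case <- rep(TRUE, n)
  if (incomplete > 0) fm$complete_case[seq_len(incomplete)] <- FALSE
  attr(fm, "feature_blocks") <- list(
    base = c(phosphoscreen:::BASE_FEATURES, "kinase_basal", "wt_vs_kd_tnf",
             "kd_vs_tnf"),
    seq_ikk = paste0("seq_ikk_", sprintf("p%02d", 1:31)),
    seq_tnf = paste0("seq_tnf_", sprintf("p%02d", 1:31)))
  class(fm) <- c("feature_matrix", "data.frame")
  attr(fm, "positives") <- fm$site_id[seq_len(n_pos)]
  fm
}

test_that("downsampling caps negatives at four times the positive class", {
  fm <- toy_feature_matrix(n_pos = 10, n_neg = 1000)
  pos <- attr(fm, "positives")
  sets <- assemble_training_sets(fm, pos, forest_config())
  expect_length(sets$negatives, 40)
  expect_length(intersect(sets$positives, sets$negatives), 0)
  expect_setequal(c(sets$negatives, sets$unused_candidates),
                  setdiff(fm$site_id, pos))

  # cap not binding when candidates are scarce
  fm2 <- toy_feature_matrix(n_pos = 10, n_neg = 25)
  sets2 <- assemble_training_sets(fm2, attr(fm2, "positives"), forest_config())
  expect_length(sets2$negatives, 25)

  # determinism and positive screening
  sets3 <- assemble_training_sets(fm, pos, forest_config())
  expect_identical(sets$negatives, sets3$negatives)
  expect_error(assemble_training_sets(fm, c("absent1", "absent2"),
                                      forest_config()),
               "insufficient positives")
})

test_that("positives absent from the complete-case set are dropped with a log", {
  fm <- toy_feature_matrix(n_pos = 10, n_neg = 100, incomplete = 3)
  pos <- attr(fm, "positives")  # first 3 are incomplete
  sets <- assemble_training_sets(fm, pos, forest_config())
  expect_length(sets$positives, 7)
  expect_setequal(sets$dropped_positives, pos[1:3])
})

test_that("negative draws are uniform over the candidate pool", {
  fm <- toy_feature_matrix(n_pos = 2, n_neg = 100)
  pos <- attr(fm, "positives")
  counts <- table(unlist(lapply(1:200, function(s) {
    assemble_training_sets(fm, pos, forest_config(seed = s))$negatives
  })))
  # each of the 100 candidates drawn with probability 8/100 per run
  p <- 8 / 100
  se <- sqrt(p * (1 - p) / 200)
  expect_lt(max(abs(counts / 200 - p)), 4 * se)
})

test_that("a separable feature yields a perfect training-set AUC", {
  fm <- toy_feature_matrix(n_pos = 25, n_neg = 100, shift = 30)
  sets <- assemble_training_sets(fm, attr(fm, "positives"),
                                 forest_config(seed = 5))
  clf <- train_classifier(sets, forest_config(n_trees = 1500, tune_length = 1,
                                              seed = 5))
  expect_equal(clf$n_trees, 1500)
  roc <- evaluate_roc(clf, sets$features, sets$labels == "pos")
  expect_equal(roc$auc, 1.0)
  expect_lt(clf$oob_error, 0.05)
  # training positives outscore the median training negative
  prob <- predict(clf, sets$features)
  expect_true(all(prob[sets$labels == "pos"] >
                    median(prob[sets$labels == "neg"])))
})

test_that("permuted labels give chance-level cross-validated AUC", {
  aucs <- vapply(1:20, function(s) {
    fm <- toy_feature_matrix(n_pos = 30, n_neg = 30, shift = 0, seed = 400 + s)
    sets <- assemble_training_sets(fm, attr(fm, "positives"),
                                   forest_config(seed = s))
    clf <- train_classifier(sets, forest_config(n_trees = 100,
                                                tune_length = 2,
                                                cv_repeats = 3, seed = s))
    mean(clf$tuning$cv_auc)
  }, numeric(1))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("mtry tuning records the ROC grid and refits at the maximiser", {
  fm <- toy_feature_matrix(n_pos = 15, n_neg = 60, shift = 3)
  sets <- assemble_training_sets(fm, attr(fm, "positives"), forest_config())
  cfg <- forest_config(n_trees = 200, tune_length = 5, cv_repeats = 1,
                       seed = 6)
  clf <- train_classifier(sets, cfg)
  expect_equal(nrow(clf$tuning), length(unique(clf$tuning$mtry)))
  expect_equal(clf$mtry, clf$tuning$mtry[which.max(clf$tuning$cv_auc)])
  expect_true(all(clf$tuning$cv_auc >= 0 & clf$tuning$cv_auc <= 1))
})

test_that("AUC equals brute-force Mann-Whitney concordance", {
  set.seed(43)
  scores <- c(rnorm(12, 1), rnorm(18))   # 30-item fixture with ties possible
  scores[c(3, 17)] <- scores[c(4, 20)]   # force ties
  labels <- rep(c(TRUE, FALSE), c(12, 18))
  expect_equal(phosphoscreen:::auc_rank(scores, labels),
               oracle_concordance_auc(scores, labels), tolerance = 1e-12)
  # degenerate and perfect rankings
  expect_equal(phosphoscreen:::auc_rank(rep(1, 10), rep(c(TRUE, FALSE), 5)),
               0.5)
  expect_equal(phosphoscreen:::auc_rank(1:10, c(rep(FALSE, 5), rep(TRUE, 5))),
               1.0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  scores <- rnorm(50)
  labels <- rep(c(TRUE, FALSE), 25)
  expect_equal(phosphoscreen:::auc_rank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC curves are monotone and span the unit square", {
  set.seed(45)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), 20)
  curve <- roc_points(scores, labels)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
})

test_that("scores are 0-100 scaled with a consistent delta and rank", {
  fm <- toy_feature_matrix(n_pos = 15, n_neg = 60, shift = 3, incomplete = 5)
  cfg <- forest_config(n_trees = 150, tune_length = 1, seed = 7)
  pos <- attr(fm, "positives")
  sets_i <- assemble_training_sets(fm, pos, cfg, classifier = "ikk")
  sets_t <- assemble_training_sets(fm, pos, cfg, classifier = "tnf")
  clf_i <- train_classifier(sets_i, cfg)
  clf_t <- train_classifier(sets_t, cfg)
  scored <- score_all_sites(clf_i, clf_t, fm)
  expect_equal(nrow(scored), sum(fm$complete_case))
  expect_equal(nrow(attr(scored, "skipped")), 5)
  expect_true(all(scored$ikk_score >= 0 & scored$ikk_score <= 100))
  expect_equal(scored$delta, scored$ikk_score - scored$tnf_score,
               tolerance = 1e-9)
  expect_equal(sort(scored$rank), seq_len(nrow(scored)))
  ord <- order(scored$rank)
  expect_true(all(diff(scored$ikk_score[ord]) <= 1e-9))
})

test_that("a probability pair maps to the published score arithmetic", {
  # 0-100 scaling: p = 0.8306 / 0.762 gives scores 83.06 / 76.2, delta 6.86
  expect_equal(100 * 0.8306 - 100 * 0.762, 6.86, tolerance = 1e-9)
})

test_that("candidate ranking excludes knowns and honours the score floors", {
  scored <- data.frame(
    site_id = c("known1", "a", "b", "c", "d"),
    ikk_score = c(95, 87.8, 84.26, 83.06, 50),
    tnf_score = c(50, 92.73, 81.2, 76.2, 80),
    stringsAsFactors = FALSE)
  scored$delta <- scored$ikk_score - scored$tnf_score
  scored$rank <- rank(-scored$ikk_score)
  out <- rank_candidates(scored, known_positives = "known1")
  # published-style score pairs pass the (80, -5) floors; (50, -30) fails
  expect_equal(out$site_id, c("a", "b", "c"))
  expect_equal(out$site_id, out$site_id[order(-out$ikk_score)])
  all_known <- rank_candidates(scored, known_positives = scored$site_id)
  expect_equal(nrow(all_known), 0)

  shuffled <- scored[c(4, 2, 5, 1, 3), ]
  expect_equal(rank_candidates(shuffled, "known1")$site_id, c("a", "b", "c"))
})

test_that("manifest mismatches are rejected at prediction time", {
  fm <- toy_feature_matrix(n_pos = 10, n_neg = 40)
  cfg <- forest_config(n_trees = 50, tune_length = 1)
  sets <- assemble_training_sets(fm, attr(fm, "positives"), cfg)
  clf <- train_classifier(sets, cfg)
  expect_error(predict(clf, sets$features[, -1]), "feature mismatch")
  expect_error(evaluate_roc(clf, sets$features, rep(TRUE, nrow(sets$features))),
               "both classes")
})
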