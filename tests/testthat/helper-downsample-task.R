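# Imbalanced classification task over the package's feature layout: 30
# positives against 10,000 negatives, with four informative ratio-type
# features at a moderate shift and pure-noise sequence blocks. Used to probe
# the effect of majority-class downsampling with a strictly disjoint
# train/test split.
make_imbalanced_task <- function(seed, n_pos = 30, n_neg = 10000, shift = 2) {
  set.seed(seed)
  n <- n_pos + n_neg
  fm <- data.frame(site_id = sprintf("t%05d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (col in phosphoscreen:::BASE_FEATURES) fm[[col]] <- rnorm(n)
  lab <- rep(c(1, 0), c(n_pos, n_neg))
  fm$l2r_e1_HL <- fm$l2r_e1_HL + shift * lab
  fm$kinase_basal <- rnorm(n) + 0.5 * shift * lab
  fm$wt_vs_kd_tnf <- rnorm(n) + shift * lab
  fm$kd_vs_tnf <- rnorm(n) - shift * lab
  for (p in sprintf("p%02d", 1:31)) {
    fm[[paste0("seq_ikk_", p)]] <- rnorm(n)
    fm[[paste0("seq_tnf_", p)]] <- rnorm(n)
  }
  fm$complete_case <- rep(TRUE, n)
  attr(fm, "feature_blocks") <- list(
    base = c(phosphoscreen:::BASE_FEATURES, "kinase_basal", "wt_vs_kd_tnf",
             "kd_vs_tnf"),
    seq_ikk = paste0("seq_ikk_", sprintf("p%02d", 1:31)),
    seq_tnf = paste0("seq_tnf_", sprintf("p%02d", 1:31)))
  class(fm) <- c("feature_matrix", "data.frame")
  attr(fm, "positives") <- fm$site_id[seq_len(n_pos)]
  fm
}

# One seed of the downsampled-vs-full comparison: train each arm on the same
# 20 positives (downsampled to 80 negatives, or all ~8,000), evaluate both on
# the same held-out 10 positives + 2,000 negatives.
downsample_comparison <- function(s) {
  fm <- make_imbalanced_task(700 + s)
  pos <- attr(fm, "positives")
  set.seed(s)
  test_pos <- sample(pos, 10)
  test_neg <- sample(setdiff(fm$site_id, pos), 2000)
  train_fm <- fm[!fm$site_id %in% c(test_pos, test_neg), , drop = FALSE]
  attr(train_fm, "feature_blocks") <- attr(fm, "feature_blocks")
  train_pos <- setdiff(pos, test_pos)
  cfg_down <- forest_config(n_trees = 300, tune_length = 1, seed = s)
  cfg_full <- forest_config(n_trees = 300, tune_length = 1,
                            downsample_factor = Inf, seed = s)
  clf_down <- train_classifier(assemble_training_sets(train_fm, train_pos,
                                                      cfg_down), cfg_down)
  clf_full <- train_classifier(assemble_training_sets(train_fm, train_pos,
                                                      cfg_full), cfg_full)
  rows <- as.data.frame(fm)[match(c(test_pos, test_neg), fm$site_id), ,
                            drop = FALSE]
  labels <- c(rep(TRUE, length(test_pos)), rep(FALSE, length(test_neg)))
  c(down = evaluate_roc(clf_down, rows, labels)$auc,
    full = evaluate_roc(clf_full, rows, labels)$auc)
}

# One seed of the delta-score geometry check: simulate a screen with planted
# substrates and stimulus-only responders, train both classifiers on revealed
# positives (11 kinase / 25 stimulus), and compare mean delta per class.
delta_geometry_run <- function(s, forest_trees = 300) {
  sim <- simulate_phosphoproteome(simulation_config(
    n_sites = 800, n_ikk_substrates = 30, n_tnf_responders = 100,
    seed = 9000 + s))
  merged <- merge_replicates(sim$sites)$table
  substrates <- sim$truth$site_id[sim$truth$class == "IKK_SUBSTRATE"]
  responders <- sim$truth$site_id[sim$truth$class %in%
                                    c("IKK_SUBSTRATE", "TNF_ONLY")]
  set.seed(100 + s)
  pos_ikk <- sample(substrates, 11)
  pos_tnf <- sample(responders, 25)
  background <- window_background(merged$window)
  fm <- build_feature_matrix(
    merged,
    build_pssm(merged$window[merged$site_id %in% pos_ikk],
               background = background),
    build_pssm(merged$window[merged$site_id %in% pos_tnf],
               background = background))
  cfg <- forest_config(n_trees = forest_trees, tune_length = 1, seed = s)
  clf_ikk <- train_classifier(assemble_training_sets(fm, pos_ikk, cfg, "ikk"),
                              cfg)
  clf_tnf <- train_classifier(assemble_training_sets(fm, pos_tnf, cfg, "tnf"),
                              cfg)
  scored <- score_all_sites(clf_ikk, clf_tnf, fm)
  scored <- merge(scored, sim$truth[c("site_id", "class")], by = "site_id")
  mean(scored$delta[scored$class == "IKK_SUBSTRATE"]) >
    mean(scored$delta[scored$class == "TNF_ONLY"])
}
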