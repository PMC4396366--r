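#' Configuration for the ensemble classifiers
#'
#' Defaults follow the screen's published training protocol: forests of 1,500
#' trees, `mtry` tuned over a 5-point grid by ROC-maximising cross-validation
#' (5-fold, 3 repeats), and the majority class downsampled to at most four
#' times the positive class.
#'
#' @param n_trees Trees per forest.
#' @param tune_length Number of `mtry` grid points (1 skips tuning and uses
#'   `floor(sqrt(p))`).
#' @param downsample_factor Maximum negatives per positive.
#' @param cv_folds Cross-validation folds for tuning.
#' @param cv_repeats Cross-validation repeats for tuning.
#' @param seed Integer seed.
#' @return A validated `forest_config` list.
#' @export
forest_config <- function(n_trees = 1500, tune_length = 5,
                          downsample_factor = 4, cv_folds = 5,
                          cv_repeats = 3, seed = 1) {
  cfg <- list(n_trees = n_trees, tune_length = tune_length,
              downsample_factor = downsample_factor, cv_folds = cv_folds,
              cv_repeats = cv_repeats, seed = seed)
  check_range(cfg, "n_trees", 1, integer = TRUE)
  check_range(cfg, "tune_length", 1, integer = TRUE)
  if (!is.infinite(cfg$downsample_factor)) {
    check_range(cfg, "downsample_factor", 1)
  }
  check_range(cfg, "cv_folds", 2, integer = TRUE)
  check_range(cfg, "cv_repeats", 1, integer = TRUE)
  check_range(cfg, "seed", integer = TRUE)
  structure(cfg, class = "forest_config")
}

#' Assemble downsampled training sets
#'
#' Positives are the curated substrate (or responder) sites present in the
#' complete-case feature space; negatives are drawn uniformly without
#' replacement from the remaining complete-case sites, capped at
#' `downsample_factor` times the positive count. Set
#' `downsample_factor = Inf` to train on the full negative set.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param positives Character vector of positive site ids.
#' @param cfg A [forest_config()].
#' @param classifier `"ikk"` or `"tnf"` (selects the feature manifest).
#' @return A `training_sets` list: `positives`, `negatives`,
#'   `unused_candidates`, `features` (data frame of training rows), `labels`
#'   (factor `pos`/`neg`), `manifest`, `dropped_positives`.
#' @export
assemble_training_sets <- function(fm, positives, cfg = forest_config(),
                                   classifier = c("ikk", "tnf")) {
  classifier <- match.arg(classifier)
  cc_ids <- fm$site_id[fm$complete_case]
  usable <- intersect(positives, cc_ids)
  dropped <- setdiff(positives, usable)
  if (length(usable) < 2) {
    stop("insufficient positives: fewer than 2 curated sites are complete cases",
         call. = FALSE)
  }
  candidates <- setdiff(cc_ids, positives)
  n_neg <- min(length(candidates),
               if (is.infinite(cfg$downsample_factor)) length(candidates)
               else floor(cfg$downsample_factor * length(usable)))
  set.seed(derive_seed(cfg$seed, paste0("downsample_", classifier)))
  negatives <- sort(sample(candidates, n_neg))

  manifest <- feature_manifest(fm, classifier)
  rows <- match(c(usable, negatives), fm$site_id)
  structure(list(positives = usable, negatives = negatives,
                 unused_candidates = setdiff(candidates, negatives),
                 features = as.data.frame(fm)[rows, manifest, drop = FALSE],
                 labels = factor(rep(c("pos", "neg"),
                                     c(length(usable), length(negatives))),
                                 levels = c("neg", "pos")),
                 manifest = manifest, classifier = classifier,
                 dropped_positives = dropped),
            class = "training_sets")
}

# Rank-based AUC: identical to the normalised Mann-Whitney U statistic,
# with tied scores contributing 1/2 per pair.
auc_rank <- function(scores, is_pos) {
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  if (np == 0 || nn == 0) {
    stop("evaluation requires both classes", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

# Stratified fold assignment: each class split as evenly as possible.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train one ensemble classifier
#'
#' Selects `mtry` by maximising the mean cross-validated area under the ROC
#' curve over a `tune_length`-point grid spaced between 2 and
#' `floor(2 * sqrt(p))`, then refits a forest of `n_trees` trees on all
#' training rows at the chosen value. The class-probability estimate is the
#' fraction of trees voting for the positive class.
#'
#' @param sets A [assemble_training_sets()] result.
#' @param cfg A [forest_config()].
#' @return A `trained_classifier`: fitted forest, chosen `mtry`, per-grid-point
#'   cross-validated ROC AUC, out-of-bag error, seed and feature manifest.
#' @export
train_classifier <- function(sets, cfg = forest_config()) {
  x <- sets$features
  y <- sets$labels
  if (nlevels(droplevels(y)) < 2) {
    stop("training requires both classes", call. = FALSE)
  }
  keep <- vapply(x, function(col) stats::var(col) > 0, logical(1))
  if (!any(keep)) stop("degenerate training set: all features constant",
                       call. = FALSE)
  p <- ncol(x)

  if (cfg$tune_length == 1) {
    grid <- max(1L, floor(sqrt(p)))
    tuning <- data.frame(mtry = grid, cv_auc = NA_real_)
  } else {
    grid <- unique(pmin(p, pmax(1L, round(seq(2, max(2, floor(2 * sqrt(p))),
                                              length.out = cfg$tune_length)))))
    aucs <- matrix(NA_real_, nrow = cfg$cv_repeats * cfg$cv_folds,
                   ncol = length(grid))
    for (rep_i in seq_len(cfg$cv_repeats)) {
      set.seed(derive_seed(cfg$seed, sprintf("cv_rep_%d_%s", rep_i,
                                             sets$classifier)))
      fold <- stratified_folds(y, cfg$cv_folds)
      for (f in seq_len(cfg$cv_folds)) {
        tr <- fold != f
        if (nlevels(droplevels(y[!tr])) < 2) next
        for (g in seq_along(grid)) {
          set.seed(derive_seed(cfg$seed, sprintf("cv_fit_%d_%d_%d", rep_i, f, g)))
          fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                            ntree = cfg$n_trees,
                                            mtry = grid[g])
          prob <- stats::predict(fit, x[!tr, , drop = FALSE],
                                 type = "prob")[, "pos"]
          aucs[(rep_i - 1) * cfg$cv_folds + f, g] <-
            auc_rank(prob, y[!tr] == "pos")
        }
      }
    }
    mean_auc <- colMeans(aucs, na.rm = TRUE)
    tuning <- data.frame(mtry = grid, cv_auc = mean_auc)
    grid <- grid[which.max(mean_auc)]
  }

  set.seed(derive_seed(cfg$seed, paste0("final_fit_", sets$classifier)))
  fit <- randomForest::randomForest(x, y, ntree = cfg$n_trees, mtry = grid)
  structure(list(fit = fit, mtry = grid, tuning = tuning,
                 oob_error = unname(fit$err.rate[cfg$n_trees, "OOB"]),
                 n_trees = cfg$n_trees, seed = cfg$seed,
                 manifest = sets$manifest, classifier = sets$classifier),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("trained_classifier (%s): %d trees, mtry %d, OOB error %.4f\n",
              x$classifier, x$n_trees, x$mtry, x$oob_error))
  invisible(x)
}

#' Positive-class probabilities from a trained classifier
#' @param object A `trained_classifier`.
#' @param newdata Data frame containing the classifier's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$manifest, names(newdata))
  if (length(missing_cols)) {
    stop(sprintf("feature mismatch: missing columns %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  unname(stats::predict(object$fit,
                        newdata[object$manifest],
                        type = "prob")[, "pos"])
}

#' ROC curve and AUC on a labelled test set
#'
#' The AUC is computed by the rank (Mann-Whitney) formula and therefore
#' equals the probability that a random positive outscores a random negative,
#' counting ties as 1/2.
#'
#' @param clf A `trained_classifier`.
#' @param test_features Data frame of test rows.
#' @param test_labels Logical (positive = `TRUE`) or factor with level
#'   `"pos"`.
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
evaluate_roc <- function(clf, test_features, test_labels) {
  is_pos <- if (is.logical(test_labels)) test_labels else test_labels == "pos"
  if (all(is_pos) || !any(is_pos)) {
    stop("evaluation requires both classes", call. = FALSE)
  }
  scores <- predict(clf, test_features)
  list(curve = roc_points(scores, is_pos), auc = auc_rank(scores, is_pos))
}

#' ROC curve points from scores
#' @param scores Numeric scores (higher = more positive).
#' @param is_pos Logical labels.
#' @return Data frame `threshold`, `fpr`, `tpr`, monotone in both coordinates.
#' @export
roc_points <- function(scores, is_pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  # step only after the last tied score
  keep <- c(diff(s) != 0, TRUE)
  tpr <- cumsum(pos)[keep] / sum(is_pos)
  fpr <- cumsum(!pos)[keep] / sum(!is_pos)
  data.frame(threshold = c(Inf, s[keep]), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Score every complete-case site with both classifiers
#'
#' Scores are class probabilities on a 0-100 scale; the delta score is the
#' kinase-dependence score minus the stimulus-dependence score. Sites are
#' ranked by kinase score (descending), ties broken by delta then site id.
#'
#' @param clf_ikk,clf_tnf Trained kinase / stimulus classifiers.
#' @param fm A [build_feature_matrix()] result.
#' @return Data frame `site_id`, `ikk_score`, `tnf_score`, `delta`, `rank`;
#'   skipped incomplete sites are listed in the `skipped` attribute.
#' @export
score_all_sites <- function(clf_ikk, clf_tnf, fm) {
  cc <- fm$complete_case
  rows <- as.data.frame(fm)[cc, , drop = FALSE]
  out <- data.frame(site_id = rows$site_id,
                    ikk_score = 100 * predict(clf_ikk, rows),
                    tnf_score = 100 * predict(clf_tnf, rows),
                    stringsAsFactors = FALSE)
  out$delta <- out$ikk_score - out$tnf_score
  ord <- order(-out$ikk_score, -out$delta, out$site_id)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "skipped") <- data.frame(
    site_id = fm$site_id[!cc],
    reason = rep("incomplete SILAC ratio coverage", sum(!cc)),
    stringsAsFactors = FALSE)
  out
}

#' Rank novel substrate candidates
#'
#' Removes the curated positives and keeps sites whose kinase score and delta
#' score clear the configured floors, sorted by kinase score (descending),
#' ties broken by delta (descending) then site id.
#'
#' @param scored A [score_all_sites()] result.
#' @param known_positives Site ids to exclude.
#' @param min_ikk_score Minimum kinase score (0-100 scale).
#' @param min_delta Minimum delta score.
#' @return The filtered, ordered data frame.
#' @export
rank_candidates <- function(scored, known_positives = character(0),
                            min_ikk_score = 80, min_delta = -5) {
  if (nrow(scored) == 0) stop("scored list is empty", call. = FALSE)
  out <- scored[!scored$site_id %in% known_positives &
                  scored$ikk_score >= min_ikk_score &
                  scored$delta >= min_delta, , drop = FALSE]
  out <- out[order(-out$ikk_score, -out$delta, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
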