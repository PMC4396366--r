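#' Configuration for regulated-site calling
#'
#' Defaults follow the screen's published settings: fudge factor `s0 = 0.6`,
#' 500 permutations for FDR estimation, and a regulated call requiring FDR
#' < 0.05 together with a fold change beyond 1.5.
#'
#' @param s0 Fudge factor added to the standard error in the moderated
#'   statistic.
#' @param n_permutations Number of sign-flip permutations.
#' @param fdr_threshold q-value threshold for a regulated call.
#' @param fold_change_threshold Fold-change gate (applied as `> fc` up or
#'   `< 1/fc` down).
#' @param inhibition_threshold Minimum fraction of the stimulus-induced
#'   increase that must be lost under the inhibitor arm.
#' @param inhibition_scale `"log2"` measures inhibition on the log2-excess
#'   scale, `"ratio"` on the raw ratio-excess scale.
#' @param min_replicates Minimum finite replicate ratios for a site to be
#'   scored.
#' @param seed Integer seed for permutation sampling.
#' @return A validated `regulation_config` list.
#' @export
regulation_config <- function(s0 = 0.6, n_permutations = 500,
                              fdr_threshold = 0.05,
                              fold_change_threshold = 1.5,
                              inhibition_threshold = 0.90,
                              inhibition_scale = c("log2", "ratio"),
                              min_replicates = 2, seed = 1) {
  cfg <- list(s0 = s0, n_permutations = n_permutations,
              fdr_threshold = fdr_threshold,
              fold_change_threshold = fold_change_threshold,
              inhibition_threshold = inhibition_threshold,
              inhibition_scale = match.arg(inhibition_scale),
              min_replicates = min_replicates, seed = seed)
  check_range(cfg, "s0", 0)
  check_range(cfg, "n_permutations", 1, integer = TRUE)
  check_range(cfg, "fdr_threshold", 0, 1)
  check_range(cfg, "fold_change_threshold", 1)
  check_range(cfg, "inhibition_threshold", 0, 1)
  check_range(cfg, "min_replicates", 2, integer = TRUE)
  check_range(cfg, "seed", integer = TRUE)
  structure(cfg, class = "regulation_config")
}

#' Moderated one-sample statistic
#'
#' `d = mean(x) / (se(x) + s0)` where `se` is the standard error of the mean
#' and `s0` a small fudge factor stabilising low-variance sites.
#'
#' @param x Numeric vector of replicate log2 ratios (>= 2 finite values).
#' @param s0 Fudge factor.
#' @return The moderated statistic `d`.
#' @export
#' @examples
#' moderated_statistic(c(0.8, 1.2, 1.0), s0 = 0.6)
moderated_statistic <- function(x, s0 = 0.6) {
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    stop("insufficient replication: at least 2 finite values required",
         call. = FALSE)
  }
  mean(x) / (stats::sd(x) / sqrt(length(x)) + s0)
}

# Row-wise moderated statistic for a sites x replicates matrix with NAs.
row_moderated <- function(X, s0) {
  n <- rowSums(is.finite(X))
  m <- rowMeans(X, na.rm = TRUE)
  ss <- rowSums((X - m)^2, na.rm = TRUE)
  se <- sqrt(ss / pmax(n - 1, 1)) / sqrt(n)
  m / (se + s0)
}

# Extract the sites x replicates log2 ratio matrix for one contrast.
log2_ratio_matrix <- function(table, experiment, pair) {
  cols <- grep(sprintf("^Ratio %s Exp%d R[0-9]+$", pair, experiment),
               names(table), value = TRUE)
  if (!length(cols)) {
    stop(sprintf("no replicate ratio columns for pair %s in experiment %d",
                 pair, experiment), call. = FALSE)
  }
  cols <- cols[order(as.integer(sub("^.* R", "", cols)))]
  X <- log2(as.matrix(as.data.frame(table)[cols]))
  rownames(X) <- table$site_id
  X
}

# Sign-flip patterns as a n_perm x n_rep matrix of +-1. Enumerates all 2^n
# patterns when feasible within the budget, otherwise samples distinct
# patterns without replacement.
sign_patterns <- function(n_rep, n_permutations, seed) {
  total <- 2^n_rep
  if (total <= n_permutations) {
    idx <- 0:(total - 1)
  } else {
    set.seed(seed)
    if (n_rep <= 30) {
      idx <- sample.int(total, n_permutations) - 1
    } else {
      return(matrix(sample(c(-1, 1), n_permutations * n_rep, replace = TRUE),
                    nrow = n_permutations))
    }
  }
  bits <- vapply(seq_len(n_rep), function(b) bitwAnd(idx, 2^(b - 1)) > 0,
                 logical(length(idx)))
  matrix(ifelse(bits, -1, 1), nrow = length(idx), ncol = n_rep)
}

#' Permutation-based FDR for one contrast
#'
#' Scores every site of a replicate-level table on one SILAC contrast with the
#' moderated statistic and estimates q-values from a sign-flip permutation
#' null: each permutation flips the signs of a fixed replicate subset across
#' all sites, and the q-value at threshold `|d|` is the median permutation
#' count of null statistics at or beyond the threshold divided by the observed
#' count, clipped to \[0, 1\] and made monotone non-increasing in `|d|`. When
#' `2^n_replicates` does not exceed `n_permutations` the full sign-flip
#' enumeration is used, making the estimate exact and deterministic.
#'
#' The null pool is restricted to sites with a complete replicate set: a site
#' with missing replicates is invariant under every sign pattern that is (up
#' to a global flip) the identity on its observed columns, so its own signal
#' would otherwise re-enter the null and inflate the q-values of every site
#' below it. Null counts are rescaled by the ratio of scored to
#' complete-replicate sites; sites with at least `min_replicates` finite
#' ratios are still scored.
#'
#' @param table A `site_table` with replicate-level ratio columns.
#' @param cfg A [regulation_config()].
#' @param experiment Experiment carrying the contrast (default 1).
#' @param pair Channel pair of the contrast (default `"H/L"`, stimulus versus
#'   unstimulated control in the default design).
#' @return A data frame (one row per scored site): `site_id`, `n_obs`, `d`,
#'   `mean_log2_fc`, `fold_change`, `q_value`. Sites with fewer than
#'   `min_replicates` finite ratios are skipped and listed in the `skipped`
#'   attribute.
#' @export
permutation_fdr <- function(table, cfg = regulation_config(),
                            experiment = 1, pair = "H/L") {
  X <- log2_ratio_matrix(table, experiment, pair)
  n_obs <- rowSums(is.finite(X))
  keep <- n_obs >= cfg$min_replicates
  skipped <- data.frame(site_id = rownames(X)[!keep],
                        reason = sprintf("only %d finite replicate ratios",
                                         n_obs[!keep]),
                        stringsAsFactors = FALSE)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0) {
    res <- data.frame(site_id = character(0), n_obs = integer(0),
                      d = numeric(0), mean_log2_fc = numeric(0),
                      fold_change = numeric(0), q_value = numeric(0))
    attr(res, "skipped") <- skipped
    return(res)
  }

  d <- row_moderated(X, cfg$s0)
  abs_d <- abs(d)
  thr <- sort(unique(abs_d))
  # observed exceedance counts per threshold
  obs_sorted <- sort(abs_d)
  obs_count <- nrow(X) - findInterval(thr, obs_sorted, left.open = TRUE)

  complete <- rowSums(is.finite(X)) == ncol(X)
  if (!any(complete)) complete <- rep(TRUE, nrow(X))
  X_null <- X[complete, , drop = FALSE]
  scale <- nrow(X) / nrow(X_null)

  S <- sign_patterns(ncol(X), cfg$n_permutations, cfg$seed)
  null_counts <- matrix(0L, nrow = nrow(S), ncol = length(thr))
  for (b in seq_len(nrow(S))) {
    Xb <- sweep(X_null, 2, S[b, ], `*`)
    db <- sort(abs(row_moderated(Xb, cfg$s0)))
    null_counts[b, ] <- length(db) - findInterval(thr, db, left.open = TRUE)
  }
  med_null <- apply(null_counts, 2, stats::median)
  q_thr <- pmin(pmax(scale * med_null / obs_count, 0), 1)
  # step-down monotonization from the largest |d|
  if (length(thr) > 1) {
    for (i in (length(thr) - 1):1) q_thr[i] <- max(q_thr[i], q_thr[i + 1])
  }
  q <- q_thr[match(abs_d, thr)]

  m <- rowMeans(X, na.rm = TRUE)
  res <- data.frame(site_id = rownames(X), n_obs = rowSums(is.finite(X)),
                    d = unname(d), mean_log2_fc = unname(m),
                    fold_change = unname(2^m), q_value = unname(q),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Flag regulated sites
#'
#' A site is regulated when its q-value is below the FDR threshold and its
#' fold change exceeds the gate (`> fc` for upregulation, `< 1/fc` for
#' downregulation).
#'
#' @param results Data frame from [permutation_fdr()].
#' @param cfg A [regulation_config()].
#' @return `results` with added columns `direction` (`"up"`/`"down"`) and
#'   `regulated` (logical).
#' @export
call_regulated <- function(results, cfg = regulation_config()) {
  fc <- results$fold_change
  results$direction <- ifelse(results$mean_log2_fc >= 0, "up", "down")
  results$regulated <- results$q_value < cfg$fdr_threshold &
    (fc > cfg$fold_change_threshold | fc < 1 / cfg$fold_change_threshold)
  results
}

#' Inhibitor-sensitive subset of upregulated sites
#'
#' Among stimulus-upregulated sites, retains those whose stimulus-induced
#' log2 excess is reduced by at least `inhibition_threshold` when the
#' inhibitor is applied before stimulation (experiment 2 of the default
#' design: `M/L` carries the stimulus excess over control, `H/L` the excess
#' remaining under inhibitor plus stimulus). The inhibition fraction is
#' `1 - excess_inhibitor / excess_stimulus`, clipped to \[0, 1\]; with
#' `inhibition_scale = "ratio"` the excesses are measured as `ratio - 1` on
#' the natural scale instead.
#'
#' @param results Output of [call_regulated()].
#' @param merged_table Replicate-merged `site_table` (see
#'   [merge_replicates()]).
#' @param cfg A [regulation_config()].
#' @param experiment Experiment carrying the inhibitor arm (default 2).
#' @return Data frame with `site_id`, `stimulus_excess_log2`,
#'   `inhibitor_excess_log2`, `inhibition`, `retained`; sites lacking either
#'   ratio (or without a positive stimulus excess) are listed in the
#'   `excluded` attribute.
#' @export
inhibition_set <- function(results, merged_table, cfg = regulation_config(),
                           experiment = 2) {
  up_ids <- results$site_id[results$regulated & results$direction == "up"]
  df <- as.data.frame(merged_table)
  idx <- match(up_ids, df$site_id)
  stim <- log2(df[[ratio_column(experiment, "M/L")]][idx])
  inhib <- log2(df[[ratio_column(experiment, "H/L")]][idx])

  reason <- rep(NA_character_, length(up_ids))
  reason[!is.finite(stim) | !is.finite(inhib)] <- "missing inhibitor-arm ratio"
  reason[is.na(reason) & stim <= 0] <- "non-positive stimulus excess"
  ok <- is.na(reason)

  if (cfg$inhibition_scale == "log2") {
    inhibition <- 1 - inhib / stim
  } else {
    inhibition <- 1 - (2^inhib - 1) / (2^stim - 1)
  }
  inhibition <- pmin(pmax(inhibition, 0), 1)
  inhibition[!ok] <- NA_real_

  out <- data.frame(site_id = up_ids,
                    stimulus_excess_log2 = stim,
                    inhibitor_excess_log2 = inhib,
                    inhibition = inhibition,
                    retained = ok & inhibition >= cfg$inhibition_threshold,
                    stringsAsFactors = FALSE)
  out$retained[is.na(out$retained)] <- FALSE
  attr(out, "excluded") <- data.frame(site_id = up_ids[!ok],
                                      reason = reason[!ok],
                                      stringsAsFactors = FALSE)
  out
}

#' Overlap fraction between two site sets
#'
#' `|a intersect b| / |a|`.
#'
#' @param a,b Character vectors of site ids.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' overlap_fraction(c("s1", "s2", "s3", "s4"), c("s1", "s2", "s3"))
overlap_fraction <- function(a, b) {
  a <- unique(a)
  if (length(a) == 0) {
    stop("overlap undefined: first set is empty", call. = FALSE)
  }
  length(intersect(a, unique(b))) / length(a)
}
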