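# Independent oracles used across test files. These re-derive expected values
# by direct enumeration / hand formulas and never call the code paths they
# check.

# Brute-force SAM-style q-values by explicit enumeration of all 2^n sign
# patterns: per pattern, count null |d*| at or beyond each observed |d|
# threshold, take the median count over patterns, divide by the observed
# count, clip, then enforce monotonicity from the largest threshold down.
oracle_exhaustive_q <- function(X, s0) {
  d_of <- function(x) {
    x <- x[is.finite(x)]
    mean(x) / (sd(x) / sqrt(length(x)) + s0)
  }
  d <- apply(X, 1, d_of)
  abs_d <- abs(d)
  thr <- sort(unique(abs_d))
  obs <- vapply(thr, function(t) sum(abs_d >= t), numeric(1))

  n <- ncol(X)
  patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  counts <- matrix(0, nrow = nrow(patterns), ncol = length(thr))
  for (b in seq_len(nrow(patterns))) {
    db <- abs(apply(sweep(X, 2, patterns[b, ], `*`), 1, d_of))
    counts[b, ] <- vapply(thr, function(t) sum(db >= t), numeric(1))
  }
  med <- apply(counts, 2, median)
  q <- pmin(pmax(med / obs, 0), 1)
  if (length(q) > 1) {
    for (i in (length(q) - 1):1) q[i] <- max(q[i], q[i + 1])
  }
  q[match(abs_d, thr)]
}

# Pairwise concordance AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_concordance_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Hand product-limit estimator over unique event times.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Hand log-rank tabulation: O, E and hypergeometric V summed over event times.
oracle_logrank <- function(ta, ea, tb, eb) {
  times <- c(ta, tb)
  events <- c(ea, eb)
  grp <- rep(c(1, 2), c(length(ta), length(tb)))
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n1 <- sum(times >= t & grp == 1)
    n2 <- sum(times >= t & grp == 2)
    d1 <- sum(times == t & events == 1 & grp == 1)
    d2 <- sum(times == t & events == 1 & grp == 2)
    n <- n1 + n2
    d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Minimal in-memory site table with explicit replicate ratios.
# `ratios` is a named list: name "e<exp>_<pair no slash>_r<rep>" -> numeric
# vector over sites.
make_site_table <- function(n, ratios = list(), windows = NULL,
                            reverse = rep(FALSE, n),
                            contaminant = rep(FALSE, n),
                            locprob = rep(1, n)) {
  if (is.null(windows)) {
    windows <- replicate(n, paste0(
      paste(rep("A", 15), collapse = ""), "S",
      paste(rep("A", 15), collapse = "")))
  }
  df <- data.frame(site_id = sprintf("s%03d", seq_len(n)),
                   protein = sprintf("P%03d", seq_len(n)),
                   gene = sprintf("G%03d", seq_len(n)),
                   position = seq_len(n) + 30L,
                   residue = substr(windows, 16, 16),
                   window = windows,
                   localization_prob = locprob,
                   is_reverse = reverse,
                   is_contaminant = contaminant,
                   stringsAsFactors = FALSE)
  for (nm in names(ratios)) {
    parts <- strsplit(nm, "_")[[1]]
    e <- as.integer(sub("e", "", parts[1]))
    pair <- paste0(substr(parts[2], 1, 1), "/", substr(parts[2], 2, 2))
    r <- as.integer(sub("r", "", parts[3]))
    df[[ratio_column(e, pair, r)]] <- ratios[[nm]]
  }
  phosphoscreen:::new_site_table(df, default_experiment_design(),
                                 source = "fixture")
}

# Zero-noise simulation config (noise_sd_log2 must stay positive; an
# effectively-zero value realises the deterministic limit).
zero_noise_config <- function(...) {
  simulation_config(noise_sd_log2 = 1e-12, missing_rate = 0, ...)
}
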