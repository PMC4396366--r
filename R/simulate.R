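#' Configuration for the synthetic phosphoproteome generator
#'
#' Defaults describe a desk-scale screen: 2,000 sites of which 10% respond to
#' the stimulus (30 direct kinase substrates, 170 stimulus-only responders),
#' a fourfold stimulus effect, 90% loss of that effect under kinase
#' inhibition or the kinase-dead mutant, duplicate measurements, and
#' log-normal ratio noise.
#'
#' @param n_sites Total number of phosphosites.
#' @param n_ikk_substrates Number of planted direct kinase substrates.
#' @param n_tnf_responders Number of planted stimulus-only responders.
#' @param n_replicates Replicates per experiment (biological duplicates by
#'   default).
#' @param tnf_effect_log2 Mean log2 up-shift of stimulus-responsive sites.
#' @param inhibitor_knockdown_frac Fraction of the stimulus effect removed
#'   under the inhibitor / kinase-dead arms for kinase-dependent sites.
#' @param overexpression_effect_log2 Basal log2 shift of substrate sites under
#'   wild-type kinase overexpression without stimulation.
#' @param noise_sd_log2 Standard deviation of the additive Gaussian noise on
#'   log2 ratios.
#' @param missing_rate Fraction of ratio measurements dropped at random.
#' @param window_length Sequence-window length in residues (fixed at 31).
#' @param seed Integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 2000,
                              n_ikk_substrates = 30,
                              n_tnf_responders = 170,
                              n_replicates = 2,
                              tnf_effect_log2 = 2,
                              inhibitor_knockdown_frac = 0.9,
                              overexpression_effect_log2 = 1,
                              noise_sd_log2 = 0.5,
                              missing_rate = 0.05,
                              window_length = 31,
                              seed = 1) {
  cfg <- list(n_sites = n_sites, n_ikk_substrates = n_ikk_substrates,
              n_tnf_responders = n_tnf_responders, n_replicates = n_replicates,
              tnf_effect_log2 = tnf_effect_log2,
              inhibitor_knockdown_frac = inhibitor_knockdown_frac,
              overexpression_effect_log2 = overexpression_effect_log2,
              noise_sd_log2 = noise_sd_log2, missing_rate = missing_rate,
              window_length = window_length, seed = seed)
  check_range(cfg, "n_sites", 1, integer = TRUE)
  check_range(cfg, "n_ikk_substrates", 0, integer = TRUE)
  check_range(cfg, "n_tnf_responders", 0, integer = TRUE)
  check_range(cfg, "n_replicates", 1, integer = TRUE)
  check_range(cfg, "tnf_effect_log2")
  check_range(cfg, "inhibitor_knockdown_frac", 0, 1)
  check_range(cfg, "overexpression_effect_log2")
  check_range(cfg, "noise_sd_log2", 0, lower_open = TRUE)
  check_range(cfg, "missing_rate", 0, 1, upper_open = TRUE)
  check_range(cfg, "seed", integer = TRUE)
  if (cfg$window_length != 31) stop_config("window_length", "must equal 31")
  if (cfg$n_ikk_substrates + cfg$n_tnf_responders > cfg$n_sites) {
    stop_config("n_sites",
                "must be at least n_ikk_substrates + n_tnf_responders")
  }
  structure(cfg, class = "simulation_config")
}

# True log2 effect of each condition relative to the unstimulated baseline.
condition_effects <- function(class, cfg) {
  eff <- c(control = 0, inhibitor = 0, tnf = 0, tnf_inhibitor = 0,
           ikk_wt = 0, tnf_ikk_wt = 0, ikk_kd = 0, tnf_ikk_kd = 0)
  t <- cfg$tnf_effect_log2
  if (class == "TNF_ONLY") {
    eff[c("tnf", "tnf_inhibitor", "tnf_ikk_wt", "tnf_ikk_kd")] <- t
  } else if (class == "IKK_SUBSTRATE") {
    resid <- t * (1 - cfg$inhibitor_knockdown_frac)
    eff["tnf"] <- t
    eff["tnf_inhibitor"] <- resid
    eff["ikk_wt"] <- cfg$overexpression_effect_log2
    eff["tnf_ikk_wt"] <- t + cfg$overexpression_effect_log2
    eff["tnf_ikk_kd"] <- resid
  } else if (class != "NULL") {
    stop(sprintf("unknown site class '%s'", class), call. = FALSE)
  }
  eff
}

#' Simulate 31-residue sequence windows for a site class
#'
#' Substrate-class windows carry the degenerate kinase recognition motif
#' S-X-X-pS/T: a serine three residues upstream of the central phosphoacceptor
#' (which is S or T). Other classes draw all non-central residues from the
#' background distribution with a central S, T or Y at phosphoproteome-typical
#' proportions.
#'
#' @param n Number of windows.
#' @param label_class One of `"IKK_SUBSTRATE"`, `"TNF_ONLY"`, `"NULL"`.
#' @param seed Integer seed.
#' @param background Named residue probabilities over the 20 amino acids
#'   (default uniform).
#' @return Character vector of `n` windows, each 31 residues.
#' @export
simulate_sequence_windows <- function(n, label_class, seed = 1,
                                      background = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n)) {
    stop("'n' must be a non-negative integer", call. = FALSE)
  }
  if (!label_class %in% c("IKK_SUBSTRATE", "TNF_ONLY", "NULL")) {
    stop(sprintf("unknown site class '%s'", label_class), call. = FALSE)
  }
  if (n == 0) return(character(0))
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  background <- background[AA_ALPHABET]
  background <- background / sum(background)
  set.seed(seed)
  win_len <- 31L
  centre <- 16L
  mat <- matrix(sample(AA_ALPHABET, n * win_len, replace = TRUE,
                       prob = background),
                nrow = n, ncol = win_len)
  if (label_class == "IKK_SUBSTRATE") {
    mat[, centre] <- sample(c("S", "T"), n, replace = TRUE, prob = c(0.8, 0.2))
    mat[, centre - 3L] <- "S"
  } else {
    mat[, centre] <- sample(c("S", "T", "Y"), n, replace = TRUE,
                            prob = c(0.85, 0.12, 0.03))
  }
  apply(mat, 1, paste0, collapse = "")
}

#' Simulate a SILAC phosphoproteome with planted effect classes
#'
#' Draws per-replicate H/L, M/L and H/M ratios for the four-experiment design
#' as `2^(true effect difference + Normal(0, noise_sd_log2))`, where the true
#' effects follow the planted class: direct substrates gain the stimulus
#' effect, lose `inhibitor_knockdown_frac` of it under the inhibitor and the
#' kinase-dead mutant, and shift by `overexpression_effect_log2` under
#' wild-type kinase overexpression; stimulus-only responders gain the stimulus
#' effect in every stimulated arm; null sites centre at ratio 1.
#'
#' @param cfg A [simulation_config()].
#' @param design An experiment design (defaults to
#'   [default_experiment_design()]).
#' @return A list with elements `sites` (a `site_table`) and `truth` (a
#'   data frame with the class label and true per-condition log2 effects of
#'   every site).
#' @export
#' @examples
#' sim <- simulate_phosphoproteome(simulation_config(n_sites = 50, seed = 7))
#' table(sim$truth$class)
simulate_phosphoproteome <- function(cfg = simulation_config(),
                                     design = default_experiment_design()) {
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
  validate_design(design)
  n <- cfg$n_sites
  classes <- rep("NULL", n)
  if (cfg$n_ikk_substrates > 0) classes[seq_len(cfg$n_ikk_substrates)] <- "IKK_SUBSTRATE"
  if (cfg$n_tnf_responders > 0) {
    classes[cfg$n_ikk_substrates + seq_len(cfg$n_tnf_responders)] <- "TNF_ONLY"
  }

  windows <- character(n)
  for (cl in unique(classes)) {
    idx <- classes == cl
    windows[idx] <- simulate_sequence_windows(sum(idx), cl,
                                              seed = derive_seed(cfg$seed, paste0("windows_", cl)))
  }

  set.seed(derive_seed(cfg$seed, "phosphoproteome"))
  site_id <- sprintf("site_%05d", seq_len(n))
  df <- data.frame(
    site_id = site_id,
    protein = sprintf("P%05d", sample.int(9 * n, n)),
    gene = sprintf("GENE%05d", seq_len(n)),
    position = sample.int(800, n, replace = TRUE) + 15L,
    residue = substr(windows, 16, 16),
    window = windows,
    localization_prob = round(stats::rbeta(n, 9, 1), 6),
    is_reverse = FALSE,
    is_contaminant = FALSE,
    stringsAsFactors = FALSE
  )

  effects <- t(vapply(classes, condition_effects, numeric(8), cfg = cfg))
  rownames(effects) <- NULL

  for (e in 1:4) {
    ch <- design[[as.character(e)]]
    for (pair in RATIO_PAIRS) {
      num <- ch[[substr(pair, 1, 1)]]
      den <- ch[[substr(pair, 3, 3)]]
      true_l2 <- effects[, num] - effects[, den]
      for (r in seq_len(cfg$n_replicates)) {
        l2 <- true_l2 + stats::rnorm(n, 0, cfg$noise_sd_log2)
        if (cfg$missing_rate > 0) {
          l2[stats::runif(n) < cfg$missing_rate] <- NA_real_
        }
        df[[ratio_column(e, pair, r)]] <- 2^l2
      }
    }
  }

  truth <- data.frame(site_id = site_id, class = classes,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(effects))
  names(truth)[-(1:2)] <- paste0("effect_", colnames(effects))

  list(sites = new_site_table(df, design, source = "simulated",
                              n_replicates = cfg$n_replicates),
       truth = truth)
}

#' Configuration for the synthetic survival cohort
#'
#' @param n_patients Cohort size.
#' @param hazard_ratio_high_vs_low Multiplicative hazard of the high-phospho
#'   group relative to the low group.
#' @param baseline_hazard Events per day in the low group.
#' @param censor_rate Fraction of patients administratively censored.
#' @param group_separation_log2 Mean log2 separation between the groups'
#'   protein-normalized phosphosite levels.
#' @param seed Integer seed.
#' @return A validated `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_patients = 60,
                                hazard_ratio_high_vs_low = 3,
                                baseline_hazard = 1 / 1500,
                                censor_rate = 0.3,
                                group_separation_log2 = 2,
                                seed = 1) {
  cfg <- list(n_patients = n_patients,
              hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              group_separation_log2 = group_separation_log2, seed = seed)
  check_range(cfg, "n_patients", 2, integer = TRUE)
  check_range(cfg, "hazard_ratio_high_vs_low", 0, lower_open = TRUE)
  check_range(cfg, "baseline_hazard", 0, lower_open = TRUE)
  check_range(cfg, "censor_rate", 0, 1)
  check_range(cfg, "group_separation_log2", 0)
  check_range(cfg, "seed", integer = TRUE)
  structure(cfg, class = "survival_sim_config")
}

#' Simulate a survival cohort stratified by phosphosite level
#'
#' Each patient receives a protein abundance and a phosphosite abundance on
#' the log2 scale; the protein-normalized phospho level (their difference)
#' separates a high and a low group, and event times are exponential with the
#' group-specific hazard. A `censor_rate` fraction of patients is
#' administratively censored at a uniform fraction of their event time.
#'
#' @param cfg A [survival_sim_config()].
#' @return A data frame of survival records (`patient_id`,
#'   `phospho_abundance`, `protein_abundance`, `followup_time`, `event`) with
#'   the generating group in column `true_group`.
#' @export
simulate_survival_cohort <- function(cfg = survival_sim_config()) {
  if (!inherits(cfg, "survival_sim_config")) cfg <- do.call(survival_sim_config, cfg)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  n_high <- n %/% 2
  group <- rep(c("high", "low"), c(n_high, n - n_high))
  protein <- stats::rnorm(n, 20, 1)
  shift <- ifelse(group == "high", cfg$group_separation_log2 / 2,
                  -cfg$group_separation_log2 / 2)
  phospho <- protein + shift + stats::rnorm(n, 0, 0.5)
  hazard <- cfg$baseline_hazard *
    ifelse(group == "high", cfg$hazard_ratio_high_vs_low, 1)
  time <- stats::rexp(n, rate = hazard)
  event <- rep(1L, n)
  censored <- stats::runif(n) < cfg$censor_rate
  time[censored] <- time[censored] * stats::runif(sum(censored))
  event[censored] <- 0L
  data.frame(patient_id = sprintf("PT%04d", sample.int(n)),
             phospho_abundance = phospho,
             protein_abundance = protein,
             followup_time = time,
             event = event,
             true_group = group,
             stringsAsFactors = FALSE)
}
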