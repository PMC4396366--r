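write_json_log <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full substrate screen
#'
#' Orchestrates the end-to-end pipeline: simulate (or read) a phosphosite
#' table, remove decoys/contaminants, merge replicates with QC, call
#' stimulus-regulated sites with the permutation FDR, derive the
#' inhibitor-sensitive subset, build the feature space (ratio contrasts plus
#' PSSM sequence scores), train the kinase- and stimulus-dependence
#' classifiers with downsampling, evaluate both by ROC, score all
#' complete-case sites and rank delta-score candidates. All artefacts are
#' written under `out_dir` together with a JSON run log; every stage draws
#' its seed deterministically from the global seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [simulation_config()], or `NULL` when `input_path` is given.
#' @param input_path Optional path to an existing site-table TSV (requires
#'   `positives_ikk` / `positives_tnf`).
#' @param regulation A [regulation_config()].
#' @param forest A [forest_config()].
#' @param design Experiment design.
#' @param n_known_ikk,n_known_tnf Number of planted positives revealed to the
#'   trainer when running from simulation (defaults 11 and 25, the curated
#'   set sizes of the original screen).
#' @param positives_ikk,positives_tnf Curated positive site ids (required for
#'   external input; override the sampled knowns for simulated input).
#' @param candidate_min_ikk_score,candidate_min_delta Candidate-report score
#'   floors (0-100 scale).
#' @param seed Global integer seed.
#' @return Invisibly, a list with the main in-memory results and artefact
#'   paths.
#' @export
run_screen <- function(out_dir,
                       sim = simulation_config(),
                       input_path = NULL,
                       regulation = regulation_config(),
                       forest = forest_config(),
                       design = default_experiment_design(),
                       n_known_ikk = 11, n_known_tnf = 25,
                       positives_ikk = NULL, positives_tnf = NULL,
                       candidate_min_ikk_score = 80,
                       candidate_min_delta = -5,
                       seed = 1) {
  if (is.null(sim) && is.null(input_path)) {
    stop("configuration error: provide either a simulation config or an input path",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  truth <- NULL

  if (!is.null(input_path)) {
    sites <- read_site_table(input_path, design = design)
  } else {
    sim$seed <- derive_seed(seed, "simulate")
    sim_out <- simulate_phosphoproteome(sim, design = design)
    sites <- sim_out$sites
    truth <- sim_out$truth
    write_site_table(sites, art("sites.tsv"))
    write_ground_truth(truth, art("ground_truth.tsv"))
  }

  sites <- filter_decoys_contaminants(sites)
  merged_out <- merge_replicates(sites)
  merged <- merged_out$table
  write_tsv(merged_out$qc, art("replicate_qc.tsv"))

  regulation$seed <- derive_seed(seed, "permutation_fdr")
  reg <- call_regulated(permutation_fdr(sites, regulation), regulation)
  write_tsv(reg, art("regulated_sites.tsv"))
  inhib <- inhibition_set(reg, merged, regulation)
  write_tsv(inhib, art("inhibited_sites.tsv"))

  if (is.null(positives_ikk) || is.null(positives_tnf)) {
    if (is.null(truth)) {
      stop("positives_ikk and positives_tnf are required for external input",
           call. = FALSE)
    }
    substrates <- truth$site_id[truth$class == "IKK_SUBSTRATE"]
    responders <- truth$site_id[truth$class %in% c("IKK_SUBSTRATE", "TNF_ONLY")]
    set.seed(derive_seed(seed, "known_positives"))
    positives_ikk <- positives_ikk %||%
      sort(sample(substrates, min(n_known_ikk, length(substrates))))
    positives_tnf <- positives_tnf %||%
      sort(sample(responders, min(n_known_tnf, length(responders))))
  }

  background <- window_background(merged$window)
  pssm_ikk <- build_pssm(merged$window[merged$site_id %in% positives_ikk],
                         background = background)
  pssm_tnf <- build_pssm(merged$window[merged$site_id %in% positives_tnf],
                         background = background)
  write_pssm(pssm_ikk, art("pssm_ikk.tsv"))
  write_pssm(pssm_tnf, art("pssm_tnf.tsv"))

  fm <- build_feature_matrix(merged, pssm_ikk, pssm_tnf)
  write_tsv(as.data.frame(fm), art("feature_matrix.tsv"))

  forest$seed <- derive_seed(seed, "forest")
  clfs <- list()
  rocs <- list()
  for (cl in c("ikk", "tnf")) {
    pos <- if (cl == "ikk") positives_ikk else positives_tnf
    sets <- assemble_training_sets(fm, pos, forest, classifier = cl)
    clf <- train_classifier(sets, forest)
    # held-out ROC: curated positives plus candidates never drawn as
    # training negatives
    test_ids <- c(sets$positives, sets$unused_candidates)
    rows <- as.data.frame(fm)[match(test_ids, fm$site_id), , drop = FALSE]
    roc <- evaluate_roc(clf, rows, test_ids %in% sets$positives)
    write_tsv(roc$curve, art(sprintf("roc_%s.tsv", cl)))
    write_json_log(list(classifier = cl, n_trees = clf$n_trees,
                        mtry = clf$mtry, oob_error = clf$oob_error,
                        cv_tuning = clf$tuning, test_auc = roc$auc,
                        n_positives = length(sets$positives),
                        n_negatives = length(sets$negatives),
                        dropped_positives = sets$dropped_positives,
                        manifest = clf$manifest, seed = forest$seed),
                   art(sprintf("model_%s.json", cl)))
    clfs[[cl]] <- clf
    rocs[[cl]] <- roc
  }

  scored <- score_all_sites(clfs$ikk, clfs$tnf, fm)
  write_tsv(scored, art("scored_sites.tsv"))
  candidates <- rank_candidates(scored,
                                known_positives = c(positives_ikk, positives_tnf),
                                min_ikk_score = candidate_min_ikk_score,
                                min_delta = candidate_min_delta)
  report <- merge(candidates,
                  as.data.frame(merged)[c("site_id", "protein", "gene",
                                          "position", "residue", "window")],
                  by = "site_id", sort = FALSE)
  report <- report[order(report$rank), , drop = FALSE]
  write_tsv(report, art("candidates.tsv"))

  run_log <- list(
    package_version = as.character(utils::packageVersion("phosphoscreen")),
    seed = seed,
    simulation = if (is.null(input_path)) unclass(sim) else NULL,
    input_path = input_path,
    regulation = unclass(regulation),
    forest = unclass(forest),
    counts = list(sites = nrow(sites),
                  scored = nrow(reg),
                  regulated = sum(reg$regulated),
                  up = sum(reg$regulated & reg$direction == "up"),
                  down = sum(reg$regulated & reg$direction == "down"),
                  inhibited = sum(inhib$retained),
                  complete_case = sum(fm$complete_case),
                  candidates = nrow(candidates)),
    test_auc = list(ikk = rocs$ikk$auc, tnf = rocs$tnf$auc))
  write_json_log(run_log, art("run_log.json"))

  invisible(list(sites = sites, merged = merged, truth = truth,
                 regulated = reg, inhibited = inhib, feature_matrix = fm,
                 classifiers = clfs, rocs = rocs, scored = scored,
                 candidates = report, run_log = run_log, out_dir = out_dir))
}

#' Run the survival stratification
#'
#' Simulates (or reads) a survival cohort, normalizes phosphosite abundance
#' to protein abundance, selects the top-`k` and bottom-`k` patients, fits a
#' Kaplan-Meier curve per group and compares them with the log-rank test.
#'
#' @param out_dir Output directory.
#' @param sim A [survival_sim_config()], or `NULL` when `input_path` is given.
#' @param input_path Optional TSV of survival records (`patient_id`,
#'   `phospho_abundance`, `protein_abundance`, `followup_time`, `event`).
#' @param k_extreme Extreme-group size (default 20).
#' @param seed Global integer seed.
#' @return Invisibly, a list with the cohort, groups, curves and test.
#' @export
run_survival <- function(out_dir, sim = survival_sim_config(),
                         input_path = NULL, k_extreme = 20, seed = 1) {
  if (is.null(sim) && is.null(input_path)) {
    stop("configuration error: provide either a simulation config or an input path",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)

  if (!is.null(input_path)) {
    cohort <- utils::read.delim(input_path, stringsAsFactors = FALSE)
  } else {
    sim$seed <- derive_seed(seed, "survival_cohort")
    cohort <- simulate_survival_cohort(sim)
    write_tsv(cohort, art("cohort.tsv"))
  }

  normalized <- normalize_phospho(cohort)
  groups <- select_extreme_groups(normalized, k = k_extreme)
  high <- cohort[cohort$patient_id %in% groups$high, , drop = FALSE]
  low <- cohort[cohort$patient_id %in% groups$low, , drop = FALSE]
  km_high <- kaplan_meier(high$followup_time, high$event)
  km_low <- kaplan_meier(low$followup_time, low$event)
  write_tsv(as.data.frame(km_high), art("km_high.tsv"))
  write_tsv(as.data.frame(km_low), art("km_low.tsv"))
  lr <- logrank_test(high, low)

  write_json_log(list(
    package_version = as.character(utils::packageVersion("phosphoscreen")),
    seed = seed, k_extreme = k_extreme,
    n_patients = nrow(cohort), n_normalized = nrow(normalized),
    statistic = lr$statistic, p_value = lr$p_value,
    events = list(high = sum(high$event), low = sum(low$event))),
    art("survival_summary.json"))

  invisible(list(cohort = cohort, normalized = normalized, groups = groups,
                 km_high = km_high, km_low = km_low, logrank = lr,
                 out_dir = out_dir))
}
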