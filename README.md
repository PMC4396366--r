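# phosphoscreen

Computational screening for kinase substrates in multiplexed SILAC
phosphoproteomes.

Quantitative phosphoproteomics can watch thousands of phosphorylation sites
react to a stimulus at once, but it cannot by itself say *which kinase* put
each phosphate there. This package implements a screen that combines four
triple-SILAC experiments — stimulus, kinase inhibitor,
inhibitor-before-stimulus, and overexpression of an active versus a
kinase-dead mutant kinase — to rank candidate direct substrates of a
stimulus-activated kinase (the motivating system is TNF-α–activated IKKβ in
breast-cancer cells). It is aimed at proteomics bioinformaticians who have
MaxQuant-style phosphosite tables and a short list of validated substrates,
and at methodologists who want a fully simulatable testbed for this class
of screen.

The pipeline has three statistical cores:

1. **Regulated-site calling.** Each site's replicate log2 ratios
   (stimulus vs. control) are summarised by the SAM-style moderated
   statistic *d* = mean / (se + s0) with s0 = 0.6, and q-values come from a
   sign-flip permutation null (500 permutations; exact enumeration whenever
   2^replicates ≤ 500). Regulated means q < 0.05 with fold change beyond
   1.5; the inhibitor-sensitive subset additionally loses ≥ 90% of its
   stimulus-induced log2 excess when the inhibitor precedes the stimulus.
2. **Dual ensemble classifiers and the delta score.** Two random forests
   (1,500 trees, mtry tuned by ROC-maximising repeated cross-validation,
   negatives downsampled to at most 4× the positives) are trained on curated
   kinase substrates and curated stimulus responders, over 12 SILAC ratio
   features, 3 derived kinase-dependence contrasts, and 31 positional
   log-odds scores from a PSSM built on each positive set's 31-residue
   sequence windows. Every complete-case site gets a kinase score and a
   stimulus score on a 0–100 scale; delta = kinase − stimulus separates
   direct substrates from generic responders.
3. **Survival stratification.** Phosphosite abundance normalized to protein
   abundance (log-scale subtraction) stratifies the top 20 vs. lowest 20
   patients, compared by Kaplan–Meier curves and a log-rank test.

A first-class synthetic-data generator emulates the four-experiment design
with planted substrate / responder / null classes, log-normal ratio noise,
motif-bearing windows (S-X-X-pS/T for substrates) and a matched survival
cohort, so the entire pipeline runs and is tested without any download.

## Worked example

```r
library(phosphoscreen)

res <- run_screen("screen_run",
                  sim = simulation_config(n_replicates = 3),
                  forest = forest_config(n_trees = 500, tune_length = 1),
                  seed = 20)
str(res$run_log$counts)
#> List of 8
#>  $ sites        : int 2000
#>  $ scored       : int 1990
#>  $ regulated    : int 221
#>  $ up           : int 210
#>  $ down         : int 11
#>  $ inhibited    : int 14
#>  $ complete_case: int 1999
#>  $ candidates   : int 11
```

Of the 2,000 simulated sites, 1,990 carry enough replicates to score; 221
are called regulated at FDR < 0.05 and fold change > 1.5 (the simulation
planted 200 true responders, of which 30 are direct kinase substrates), and
14 upregulated sites also clear the 90% inhibition criterion. Eleven
un-curated sites pass the candidate score floors:

```r
head(res$candidates[c("site_id", "gene", "position",
                      "ikk_score", "tnf_score", "delta")], 5)
#>      site_id      gene position ikk_score tnf_score delta
#> 1 site_00030 GENE00030      497      90.0      69.2  20.8
#> 2 site_00024 GENE00024      608      89.0      56.2  32.8
#> 3 site_00014 GENE00014      372      86.4      47.0  39.4
#> 4 site_00016 GENE00016      792      84.8      73.0  11.8
#> 5 site_00003 GENE00003      308      84.0      42.4  41.6
```

Every listed site has a kinase score above 80 with a positive delta — the
signature of kinase-dependent, not merely stimulus-dependent, regulation —
and all five are planted substrates (ground truth sits in
`screen_run/ground_truth.tsv`). The run directory also contains the
regulated-site table, replicate QC (Pearson correlations of log2 ratios),
both PSSMs, the feature matrix, per-classifier model manifests and ROC
curves, scored sites, and a JSON run log with every seed and configuration.

The survival arm stratifies a simulated 60-patient cohort by
protein-normalized phosphosite level:

```r
run_survival("surv_run", seed = 7)$logrank
#> log-rank test: chi-square = 4.6603 (1 df), p = 0.03087; n = 20 vs 20
```

High-phospho patients die significantly earlier, as expected for the
generator's hazard ratio of 3 between the extreme groups.

A thin command-line wrapper with `simulate`, `screen` and `survival`
subcommands lives at `inst/scripts/phosphoscreen.R`.

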