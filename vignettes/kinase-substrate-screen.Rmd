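---
title: "Screening for kinase substrates in multiplexed SILAC phosphoproteomes"
author: "phosphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for kinase substrates in multiplexed SILAC phosphoproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The problem

A cytokine stimulus such as TNF-α activates a kinase (here the IκB kinase
subunit IKKβ) whose direct substrates are largely unknown. Triple-SILAC
phosphoproteomics measures, for thousands of phosphorylation sites at once,
relative abundance ratios between light, middle and heavy cell populations.
By combining four such triple mixes — (1) control / inhibitor / stimulus,
(2) control / stimulus / inhibitor-then-stimulus, (3) wild-type kinase /
stimulus reference / wild-type kinase + stimulus, and (4) the same with a
kinase-dead mutant — a single screen observes how every site responds to the
stimulus, to pharmacological kinase inhibition, and to overexpression of an
active or inactive kinase. The stimulated population serves as the shared
reference channel in mixes 2–4, so the four mixes jointly span nine channel
conditions (eight distinct biological states; the stimulated reference
recurs).

`phosphoscreen` implements the downstream computational screen:

1. **Regulated-site calling** — a moderated one-sample statistic with a
   sign-flip permutation FDR decides which sites respond to the stimulus.
2. **Kinase-dependence scoring** — two random-forest classifiers, one
   trained on curated kinase substrates and one on curated stimulus
   responders, score every site; the difference of the two scores (the
   *delta score*) separates direct kinase substrates from generic stimulus
   responders.
3. **Survival stratification** — protein-normalized phosphosite abundance
   stratifies patients into extreme groups compared by Kaplan–Meier curves
   and the log-rank test.

A synthetic-data generator reproduces the statistical structure of such a
screen (planted effect classes, log-normal ratio noise, motif-bearing
sequence windows, a matched survival cohort) so that every stage is testable
without any external download.

## Regulated-site calling

For each site the replicate log2 ratios of the stimulus-versus-control
contrast (mix 1, H/L) are summarised by the moderated statistic

$$ d = \frac{\bar{x}}{\mathrm{se}(\bar x) + s_0}, $$

with the fudge factor fixed at $s_0 = 0.6$. The fudge factor stabilises
sites whose replicate spread is accidentally tiny; it is a fixed constant
here, not percentile-tuned.

The null distribution comes from sign flips of the replicate columns: each
of the 500 permutations flips a fixed subset of replicates across all sites,
which is the canonical exchangeable null for the one-sample hypothesis "no
change relative to the basal level". The q-value at threshold $|d|$ is the
median over permutations of the number of null statistics at or beyond the
threshold, divided by the observed count, clipped to $[0,1]$ and made
monotone by a step-down pass from the largest $|d|$. When $2^{n}$ sign
patterns exist for $n$ replicates and $2^n \le 500$, the full enumeration is
used, making the q-values exact and deterministic.

Two numerical choices deserve attention:

* **Incomplete replicate sets.** A site with $r$ of $n$ replicates observed
  is invariant under $2^{\,n-r+1}$ of the $2^n$ sign patterns (every pattern
  that is the identity, or the global flip, on its observed columns). If
  such sites entered the null pool, a single strong 2-replicate site at the
  top of the ranking would assign itself $q = 0.5$ and the monotonization
  would propagate that to the whole table. The null pool is therefore
  restricted to complete-replicate sites, with counts rescaled by the ratio
  of scored to complete sites; sites with at least two finite replicates are
  still scored.
* **Few replicates.** With duplicates only four sign patterns exist, half of
  which preserve every statistic, so permutation q-values cannot resolve
  below roughly 0.5: the regulated-site stage is meaningfully powered from
  triplicates upward, and the examples in this package use triplicates. FDR
  estimates under these granularity limits err on the conservative side,
  never the anti-conservative one.

A site is called **regulated** when $q < 0.05$ and its fold change exceeds
1.5 (above 1.5 up, below 1/1.5 down). Among upregulated sites, the
**inhibitor-sensitive subset** retains sites whose stimulus-induced log2
excess shrinks by at least 90% when the inhibitor precedes the stimulus
(mix 2: M/L carries the stimulus excess, H/L the excess remaining under
inhibition). The 90% criterion is applied on the log2-excess scale by
default — symmetric in up/down regulation and robust to the choice of
reference channel — with a raw ratio-excess alternative behind
`regulation_config(inhibition_scale = "ratio")`.

```{r, eval = FALSE}
cfg <- regulation_config()            # s0 = 0.6, 500 permutations,
                                      # FDR < 0.05, FC > 1.5, inhibition 90%
reg <- call_regulated(permutation_fdr(sites, cfg), cfg)
inhib <- inhibition_set(reg, merge_replicates(sites)$table, cfg)
```

## The feature space

Classification uses, per site:

* the **12 base ratios** — log2 of H/L, M/L and H/M in each of the four
  mixes (replicate-merged by the median of log2 ratios, back-transformed;
  the median is robust and treats up- and down-regulation symmetrically);
* three **derived kinase-dependence contrasts**: the basal effect of kinase
  overexpression without stimulation ($-\log_2(\text{M/L})$ of mix 3), the
  wild-type-versus-kinase-dead contrast under stimulation
  ($\log_2(\text{H/M})_3 - \log_2(\text{H/M})_4$), and the kinase-dead arm
  against the stimulus alone ($\log_2(\text{H/M})_4$);
* **31 positional sequence scores** under a position-specific scoring matrix
  (PSSM) built from the classifier's own positive set: per-position residue
  probabilities with pseudocount 1 over the 21-letter alphabet (20 amino
  acids plus the terminal pad `_`), log2-odds against the background residue
  frequencies of the full window set. The 31 positions are exposed as
  separate features rather than a single summed score, so the forest can
  exploit positional structure such as the degenerate S-X-X-pS/T
  recognition motif.

Only **complete cases** — sites quantified in all four mixes — are eligible
for training and scoring; there is no imputation. Each classifier sees the
15 ratio-type features plus its own sequence block (46 features).

## Classifier training and the delta score

Both classifiers are random forests of 1,500 trees. Because validated
positives number in the tens while candidate negatives number in the
thousands, the negative class is **downsampled**: negatives are drawn
uniformly without replacement from the complete-case non-positives, at most
four per positive. `mtry` is tuned over a five-point grid between 2 and
$\lfloor 2\sqrt{p} \rfloor$ by maximising the cross-validated area under
the ROC curve (5-fold, 3 repeats — chosen over bootstrap resampling for
determinism and speed); the final forest is refit on all training rows at
the chosen value. The class-probability estimate is the fraction of trees
voting positive, reported on a 0–100 scale. AUC is computed by the rank
(Mann–Whitney) formula throughout, so it equals the pairwise concordance
probability by construction.

Every complete-case site then receives a kinase score, a stimulus score and
their difference, the **delta score**. Direct substrates should score high
on the kinase axis without an offsetting stimulus-only signal, so candidate
reporting keeps sites with kinase score ≥ 80 and delta ≥ −5 (floors chosen
to reproduce the geometry of published candidate lists, exposed as
configuration), excludes the curated positives, and orders by kinase score,
ties broken by delta and then site id.

ROC evaluation uses a strictly disjoint train/test split; where an
evaluation includes the training positives (as the original protocol did),
the resulting AUC is read as a training-set quantity, not a generalisation
estimate.

## The synthetic-data generator

`simulate_phosphoproteome()` draws every ratio as
$2^{(\text{true effect difference} + \mathcal N(0, \sigma))}$ — additive
Gaussian noise on log2 ratios, the standard SILAC error model. Planted
classes fix the true effects: direct substrates gain the stimulus effect,
lose 90% of it under the inhibitor and the kinase-dead mutant, and shift
under wild-type overexpression; stimulus-only responders gain the stimulus
effect in every stimulated arm; null sites sit at ratio 1. Defaults (chosen
once, as study conditions, and not revisited): 2,000 sites, 30 substrates
and 170 stimulus-only responders (a deliberately enriched 10% responsive
fraction — the full-scale screen's ~1% would leave a desk-scale run without
trainable classes), a fourfold stimulus effect ($\log_2 = 2$, the magnitude
reported for the validated substrate site in the source screen), knockdown
fraction 0.9, overexpression shift 1, noise SD 0.5, 5% missing ratios, and
duplicate replicates. Substrate windows carry S at position −3 and S/T at
the centre; other windows draw uniform-background residues with an S/T/Y
centre at phosphoproteome-typical proportions.

What the generator does **not** emulate: per-site latent abundance
variation (real replicate correlations of 0.65–0.83 arise from biological
spread the generator lacks — null sites here are centred at ratio 1),
isotope impurities, batch effects, peptide-level missingness that depends
on intensity, and any spectral-level artefact. Passing tests therefore
demonstrate the correctness and calibration of the statistical machinery
under its stated assumptions, not performance on real spectra.

`simulate_survival_cohort()` assigns each patient a protein abundance, a
phosphosite abundance whose protein-normalized level separates a high and a
low group, and an exponential event time with the group-specific hazard;
a configurable fraction is administratively censored.

## Survival stratification

Phosphosite abundance is normalized to protein abundance by subtraction on
the log scale (equivalently, the ratio on the natural scale), patients
missing either value are dropped with a logged reason, and the top 20
versus bottom 20 patients by normalized level (ties broken by patient id
for determinism) are compared with the product-limit estimator and the
standard unweighted log-rank test (hypergeometric variance, chi-square with
one degree of freedom). Kaplan–Meier and log-rank computations are
delegated to the `survival` package behind this interface and are verified
against hand product-limit and O/E/V tabulations in the test suite.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data at
sizes chosen to be statistically informative on a single CPU: 2,000-site
screens with triplicates for FDR calibration and planted-effect recovery
(complete replicate designs — no missing ratios — so that q-value behaviour
is assessed away from the granularity limits discussed above); a
30-positive / 10,000-negative task with four moderately informative
features for the downsampling comparison (300-tree forests; the tree count
does not drive this comparison and the default configuration keeps 1,500);
twenty 800-site screens for the delta-score geometry; 200 null cohorts for
the log-rank type-I rate. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch under a
user-supplied seed.

## Known limitations

* Permutation q-values are granular for small replicate counts
  (see above); duplicates alone cannot reach $q < 0.05$.
* The "13 SILAC ratios" sometimes quoted for complete-case tables does not
  decompose into the 3 × 4 channel-pair structure; this package exposes the
  12 base ratios plus the three derived contrasts and does not invent a
  thirteenth.
* The candidate-report score floors (80, −5) are a reconstruction of an
  unpublished decision rule and should be treated as configuration, not
  doctrine.
* Localization classes use the field convention (I ≥ 0.75, II ≥ 0.5,
  boundary to the higher class); the delta-score cut used by upstream
  search software is consumed, not recomputed.
* Bit-identical reproduction across random-forest library versions is not
  promised; stochastic quantities are validated against tolerances, not
  byte equality.
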