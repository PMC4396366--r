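Package: phosphoscreen
Title: Kinase Substrate Screening from Multiplexed SILAC Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational screen for kinase substrates from triple-SILAC
    phosphoproteomics. Calls stimulus-regulated phosphorylation sites with a
    moderated one-sample statistic and a sign-flip permutation false discovery
    rate, builds per-site feature spaces combining SILAC ratio contrasts with
    position-specific sequence scores over 31-residue windows, trains paired
    random-forest classifiers (kinase dependence versus stimulus dependence)
    with majority-class downsampling, and ranks candidate substrates by the
    score difference between the two classifiers. Includes a survival
    stratification of patients by protein-normalized phosphosite abundance
    (Kaplan-Meier, log-rank) and a synthetic-data generator that emulates the
    four-experiment SILAC design for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
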