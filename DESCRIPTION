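Package: neutroChisq
Title: Neutrosophic Chi-Square Test of Homogeneity for Multinomial Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chi-square testing of the equality of several independent
    multinomial distributions when the counts carry a measure of
    indeterminacy, following the neutrosophic-statistics formulation in
    which a statistic Q is reported as an interval [Q_L, Q_U] driven by an
    indeterminacy measure I in [I_L, I_U]. Provides S4 containers for
    count tables and interval-valued (neutrosophic) quantities, pooled
    probability estimation, the interval Pearson statistic in both the
    specified-probability and estimated-probability regimes, a
    trichotomous reject / do-not-reject / indeterminate decision rule, a
    deterministic indeterminacy sweep, seeded Monte Carlo calibration of
    type-I error and power, and a DNA front end that derives nucleotide
    (A, C, G, T) count tables from FASTA sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
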