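Package: hrdscar
Title: Genomic Scar Scoring and HRD Biomarker Analysis
Version: 0.1.0
Authors@R: person("Kira", "Larsen", email = "klarsen@example.org",
    role = c("aut", "cre"))
Description: Computes homologous recombination deficiency (HRD) genomic scar
    scores from allele-specific copy-number segment profiles: loss of
    heterozygosity (LOH), telomeric allelic imbalance (TAI) and large-scale
    state transitions (LST), with the HRD score as their sum. Provides cohort
    stratification by HRD score, a TPM-based differential-expression filter
    cascade (fold change, BH-adjusted p, expression level, MAD), survival and
    correlation statistics (Kaplan-Meier, log-rank, ROC/AUC, rank-based
    tests), a seeded synthetic-data generator with exact planted ground truth,
    and a command-line pipeline chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
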