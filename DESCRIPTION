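Package: mirscreen
Title: Pooled qPCR MicroRNA Array Screening, Seed-Site Target Prediction
    and Cohort Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for pooled low-density qPCR microRNA array
    screens and their downstream interpretation. Ingests Cq tables,
    calls detection, computes M/A log-fold changes, removes
    intensity-dependent bias by per-plate cyclic loess, and flags
    differential microRNAs with an adaptive cutoff fitted by quadratic
    polynomial quantile regression at the 0.05/0.95 quantiles. Predicts
    microRNA seed sites (nucleotides 2-8) on annotated transcripts with
    0-2 mismatches and 3'-supplementary pairing scores, tests seed-site
    enrichment in regulated gene sets by one-sided Wilcoxon rank-sum
    (exact for small samples), quantifies validation qPCR by the
    2^-delta-delta-Cq method with multi-reference normalization, and
    fits sex-by-treatment interaction models, pairwise contrasts,
    banded Spearman correlations and adjusted association regressions
    for mother-offspring cohorts. Seeded generators simulate every
    input with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
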