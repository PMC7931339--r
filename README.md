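# mirscreen

Analysis toolkit for pooled low-density qPCR microRNA array screens
and their downstream interpretation, written for placental / perinatal
transcriptomics studies that screen two pooled samples (control vs
intervention), predict microRNA targets, validate candidates by
RT-qPCR, and relate expression to cohort outcomes.

## What it does

**Screening without replicates.** A pooled screen yields one Cq per
assay and group. `mirscreen` computes expression-scale log fold
changes `M = Cq(Con) − Cq(N3)` and abundance values
`A = (Cq(Con)+Cq(N3))/2`, removes intensity-dependent bias with
per-plate cyclic loess of M on A, and flags differential microRNAs
with an *adaptive cutoff*: quadratic polynomial quantile-regression
curves fitted at the 0.05 and 0.95 quantiles of M given A by pinball-
loss minimization,

    q_tau(A) = argmin_beta  sum_i rho_tau( M_i − beta0 − beta1 A_i − beta2 A_i² )

so the flagging envelope widens wherever the measurement noise does.
Assays detected in only one group are classed `n3_only`/`con_only`;
inclusion–exclusion bookkeeping and printed-style percentages come
from `venn_summary()`.

**Target prediction.** `find_seed_sites()` scans transcripts for
7-nt windows pairing with microRNA nucleotides 2–8 (0–2 mismatches,
optional G:U wobble), annotates 5'UTR/CDS/3'UTR position and distance
to the 3'UTR, scores 3'-supplementary pairing (miRNA nt 13–16), and
renders fixed-width duplex alignments. `wilcoxon_enrichment()` tests
whether regulated genes carry higher binding scores than background
(one-sided rank-sum, exact by enumeration for pooled n ≤ 12).

**Validation and cohort statistics.** `relative_expression()`
implements 2^−ΔΔCq with multi-reference normalization and a
calibrator cell fixed at 100%; `fit_group_sex_models()` fits OLS
models with and without a sex×group interaction plus the four pairwise
cell contrasts; `association_model()` fits unadjusted (Model 1) and
confounder-adjusted (Model 2) regressions reporting beta, 95% CI and
p; `spearman_banded()` gives exact-small-n Spearman correlations with
weak/moderate/strong banding.

**Simulation.** `simulate_cq_array()`, `simulate_transcripts()` and
`simulate_cohort()` generate every input with ground-truth manifests
(planted effects, planted sites, planted betas), and
`run_pipeline()` drives the whole chain from a YAML config with a
reproducible run manifest.

## Worked example

Screen a simulated 667-assay array with ten planted 2-cycle effects:

```r
library(mirscreen)

sim <- simulate_cq_array(
  de_spec = setNames(c(rep(2, 5), rep(-2, 5)),
                     sprintf("assay_%04d", 101:110)),
  seed = 42)
res <- classify_and_summarize(sim$cq)
res$venn
#> Screened assays: 667
#> Detected: Con 667 (100.0%), N3 666 (99.9%)
#> Common 666 (99.9%), union 667 (100.0%)
#> Differential: 64 (9.6%) = 0 N3-only + 1 Con-only + 63 common
#>   common differential: 32 up + 31 down (9.4%)

subset(res$screen, assay_id == "assay_0102",
       select = c(M_norm, q_high, call, signed_fc, median_cq))
#>     M_norm q_high call signed_fc median_cq
#> 102   2.00  0.574   up      4.04      17.7
```

The planted assays exceed the fitted 0.95 quantile curve (`q_high`)
and are called `up` with signed fold change `2^M` (here ≈ 4, the
planted 2-cycle effect); the ~10% background flag rate is the
two-tailed 0.05/0.95 envelope by construction — this is an
explorative screen feeding a validation stage, not an FDR-controlled
discovery list.

Scan a transcript carrying a planted miR-99a site:

```r
m99 <- mature_mirna("hsa-miR-99a", "AACCCGUAGAUCCGAUCUUGUG")
tsim <- simulate_transcripts(
  n_genes = 3, mirnas = list(`hsa-miR-99a` = m99),
  plant_spec = data.frame(gene = 1, mirna_id = "hsa-miR-99a",
                          mismatches = 0),
  seed = 7)
hits <- find_seed_sites(m99, tsim$transcripts$gene_001, max_mismatch = 1)
hits[, c("start", "end", "region", "mismatches", "site_seq")]
#>   start end region mismatches site_seq
#> 1   459 465   3UTR          0  UACGGGU

cat(render_alignment(m99, tsim$transcripts$gene_001, hits[1, ]))
#> gene_001     5'-UAUAUCCACUGACUUACGGGUA-3'
#>                  * *    * **  *******
#> hsa-miR-99a  3'-GUGUUCUAGCCUAGAUGCCCAA-5'
#>                               ^^^^^^^   (seed)

wilcoxon_enrichment(c(5, 6, 7), c(1, 2, 3))
#> One-sided Wilcoxon rank-sum (regulated > background), exact path
#> n = 3 vs m = 3, W = 15 (U = 9), p = 0.05
```

The seven asterisks over the seed span mark the perfect
Watson–Crick seed duplex; `p = 0.05` is the exact 1/20 from
enumerating all C(6,3) group assignments.

## Documentation

The methods vignette (`vignettes/mirscreen-methods.Rmd`) describes
the models, parameter defaults and their rationale, numerical
choices, what the simulators do and do not emulate, and known
limitations.
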