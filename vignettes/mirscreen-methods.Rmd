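---
title: "Methods and design of mirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mirscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

# Scope

`mirscreen` implements the computational chain behind a pooled
low-density qPCR microRNA screen of placental tissue and its downstream
interpretation: differential-expression calling without replicates,
microRNA seed-site prediction on target transcripts, seed-site
enrichment testing, validation qPCR quantification, and the
sex-by-treatment association statistics of a mother--offspring cohort.
Every input can be simulated with seeded generators carrying
ground-truth manifests, so the whole chain is testable without any
external data.

# The screening model

A low-density array measures one quantification cycle (Cq) per assay
and pool. Cq is inversely proportional to log2 template abundance, so
for a control pool and an intervention (N3) pool the log2 fold change is

$$M = \mathrm{Cq}_{\mathrm{Con}} - \mathrm{Cq}_{\mathrm{N3}},
\qquad A = \tfrac{1}{2}(\mathrm{Cq}_{\mathrm{Con}} +
\mathrm{Cq}_{\mathrm{N3}}),$$

with positive $M$ meaning higher expression in the intervention pool.
This sign convention matters: a formula written on the Cq scale as
"N3 minus Con" flips sign on the expression scale, and the package
pins the expression-scale orientation so that reported fold changes of
up-regulated microRNAs are positive. Down-regulation is encoded as a
negative ratio ($-2^{-M}$ for $M<0$), so the magnitude of the signed
fold change is never below 1.

## Detection

A well is detected when its Cq is present, not flagged
"Undetermined", and strictly below `cq_max`. The protocol runs 40
cycles, and published screens of this design report Cq values up to
about 37.4, so the default `cq_max = 40` excludes only reactions that
never crossed threshold within the run. Assays detected in exactly one
pool cannot have an $M$ value; they are classified `n3_only` /
`con_only` and counted as differential alongside the flagged common
assays.

## Cyclic loess normalization

Pooled single-pair designs show intensity-dependent bias: $M$ drifts
with $A$, typically at high Cq where amplification efficiency
degrades. The package removes this by fitting a loess curve of $M$ on
$A$ separately per plate (assays are split across two 384-well plates
with separate master mixes) and subtracting the fit. With exactly two
samples, the general cyclic scheme over sample pairs reduces to
repeated $M$-on-$A$ passes; the default is 3 passes with span 0.7 and
local degree 1, and plates with fewer than 10 defined points fall back
to median-centering with a warning.

A note on idempotence: a loess smoother is a linear *shrinkage*
operator, not a projection, and local-linear smoothers have small
negative eigenvalues. Consequently no finite iteration makes
normalization exactly idempotent -- iterating fit-subtract drives the
residual trend down to the smoother's noise floor (a few hundredths of
a cycle on unit-noise data) and then slowly diverges. We therefore fix
a small pass count and state the achievable property instead: the
dominant planted bias is removed in the first pass (residual trend
below 10% of the planted bias in the test suite), and a second
normalization changes points by an order of magnitude less than the
bias removed. Claims of exact idempotence for loess-based
normalization are not attainable by any implementation and we do not
make them.

## Adaptive cutoff by polynomial quantile regression

Without replicates there is no variance estimate per assay, so a fixed
fold-change threshold either drowns in high-Cq noise or wastes power
at low Cq. The screen instead fits quadratic quantile-regression
curves of normalized $M$ on $A$ at $\tau = 0.05$ and $0.95$ and flags
assays strictly outside the envelope. The curve at quantile $\tau$
minimizes the pinball loss

$$\sum_i \rho_\tau\big(M_i - \beta_0 - \beta_1 A_i - \beta_2
A_i^2\big), \qquad \rho_\tau(r) = r\,(\tau - \mathbf{1}\{r<0\}).$$

The fit is computed in two stages: a quasi-Newton descent on a
smoothed pinball loss ($\rho$ replaced by
$\tau r + \varepsilon\,\mathrm{softplus}(-r/\varepsilon)$ with
$\varepsilon$ shrunk from 1 to $10^{-4}$), followed by an exact polish
exploiting the linear-programming structure of quantile regression: a
minimizer interpolates $\mathrm{degree}+1$ observations, so the polish
enumerates interpolating triples among the points nearest the smoothed
curve and keeps the lowest exact loss. On $n = 50$ the result matches
an exhaustive enumeration of all $\binom{50}{3}$ interpolating bases
to $10^{-8}$, and the LP coverage bound holds: at most 3 points sit on
each curve, so the fraction strictly below the $\tau$ curve is within
$3/n$ of $\tau$. The predictor is rescaled to $[-1,1]$ before building
the polynomial basis for conditioning; a rank-deficient design
(constant $A$) raises an error rather than returning an arbitrary
curve. Points within $10^{-8}$ of a curve count as inside.

By construction the two-tailed envelope flags about 10% of null
assays; that is the intended operating point of an *explorative*
screen feeding a validation stage, not a false-discovery-controlled
discovery list.

## Count bookkeeping

`venn_summary()` completes the inclusion--exclusion arithmetic
($n_\cup = n_{\mathrm{Con}} + n_{\mathrm{N3}} - n_\cap$), decomposes
the differential total into group-unique plus common up/down calls,
and attaches percentages of the number screened rounded half-up to one
decimal, the convention of printed tables. Feeding it the published
counts of a 667-assay screen (488/499 detected, 483 common, 12 up + 13
down) reproduces the published union (504, 75.6%) and differential
total (46, 6.9%).

# Seed-site prediction

The seed is nucleotides 2--8 of the mature microRNA. A site is a 7-nt
transcript window (read 5'$\to$3') pairing with the seed in an
antiparallel duplex; the mismatch count is the number of unpaired
positions, equivalently the Hamming distance between the window and
the reverse complement of the seed under Watson--Crick pairing. Up to
two mismatches are tolerated, reflecting how coding-region microRNA
recognition elements with imperfect seeds are reported. Design
choices:

* **Wobble pairing** G:U counts as a mismatch by default, because
  "complementary matches" in alignment figures are conventionally
  Watson--Crick; `allow_wobble = TRUE` relaxes this.
* **Coordinates** are 1-based inclusive on the transcript.
* **Region assignment** uses the window midpoint; windows straddling a
  5'UTR/CDS/3'UTR boundary are flagged `boundary`.
* **3'-supplementary score** counts Watson--Crick pairs between miRNA
  nt 13--16 and the transcript positions opposite them in a linear
  duplex anchored at the seed (miRNA position $p$ opposes transcript
  position $\mathrm{end} + 2 - p$, with a configurable loop
  allowance defaulting to 0). The window and zero-loop default follow
  the canonical supplementary-pairing convention; thermodynamic duplex
  energies are out of scope.
* **Distance to the 3'UTR** is the gap between site end and the base
  preceding the 3'UTR start, matching the verbal "98 nucleotides
  5'-adjacent to the 3'UTR" style of site descriptions.

The implementation is vectorized over windows; the test suite pins it
to a deliberately naive per-window oracle on a thousand random
transcripts and to 100% recall of planted sites.

# Enrichment testing

Server-side target-prediction scores are not reproducible locally, so
the per-gene binding score is a documented stand-in: sites weighted by
region (3'UTR 1.0, CDS 0.5, 5'UTR 0.25) and down-weighted by mismatch
count ($1/(1+\mathrm{mm})$), summed per gene. The enrichment test is
the real statistical content: a one-sided Wilcoxon rank-sum comparing
regulated genes' scores against background, exact by full enumeration
of $\binom{n+m}{n}$ assignments for pooled sizes up to 12 (midranks,
so ties are handled exactly), and a tie-corrected
continuity-corrected normal approximation beyond. "Genes over
threshold" counts regulated genes with score strictly above the
threshold (default 0.5); ties at the threshold are excluded.

# Validation quantification

Validation qPCR is quantified by $2^{-\Delta\Delta Cq}$.
$\Delta Cq$ normalizes the target to the mean Cq of the reference
panel -- the arithmetic mean of reference Cq values *is* the geometric
mean of the reference quantities on the linear scale, so no
exponentiation happens before the final step. The calibrator cell
(female control offspring) defines 100%. Two calibrator conventions
exist and differ by Jensen's inequality; the package implements both:

* `calibrator = "linear"` (default): divide each sample's
  $2^{-\Delta Cq}$ by the calibrator cell's *arithmetic mean* linear
  quantity. The calibrator's mean relative expression is then exactly
  100%, matching tables that print the calibrator as "100 ± SD".
* `calibrator = "log"`: subtract the calibrator's mean $\Delta Cq$
  (the textbook $\Delta\Delta Cq$ formula). The calibrator's
  *geometric* mean is then 100% while its arithmetic mean is slightly
  above.

Amplification efficiency is fixed at 2.0; efficiency-corrected models
are out of scope. The chain is invariant to per-sample Cq shifts
(plate offsets, input-amount differences), which the tests verify
end-to-end.

# Cohort statistics

For expression, amino-acid and hormone outcomes the package fits two
OLS models: `y ~ group + sex (+ covariates)` for the main-effect
Treatment and Sex p-values, and the same model plus `group:sex` for
the interaction p-value and four exploratory pairwise cell contrasts
(Con-M$-$Con-F, N3-M$-$N3-F, N3-F$-$Con-F, N3-M$-$Con-M). Contrast
inference uses t statistics on coefficient combinations with the
homoscedastic residual variance -- with no covariates the interaction
model is saturated and reproduces the observed cell means exactly.
Amino-acid outcomes can be natural-log transformed (`log_y`) to
address skewness; predictors are never transformed. Baseline
covariates (e.g. the week-15 maternal level) enter additively.

Association regressions come in two flavours: Model 1 is the simple
regression of outcome on predictor; Model 2 adds week-15 maternal
taurine and tryptophan, sex and group, and breastfeeding status at 4
months for postnatal outcomes. Results report $\beta$, the t-based
95% CI and the two-sided p-value, with listwise deletion per model
and the per-model n -- deliberately with *no* multiplicity
correction, mirroring the exploratory design this package serves.

Spearman correlations use midranks; the two-sided p-value is exact
(full permutation enumeration) for $n \le 9$ and a t approximation
above. Coefficients are banded by absolute value: below 0.4 weak, 0.4
to below 0.7 moderate, 0.7 and above strong -- so a reported
$R_s = 0.43$ is "moderate".

# Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the package is
tested:

* `simulate_cq_array()`: 667 assays on two alternating plates, one
  pooled sample per group; base Cq uniform on 14--36 (bracketing the
  11.8--37.4 span such screens report); well noise SD 0.25 cycles (a
  typical qPCR technical-replicate scale); optional planted delta-Cq
  effects and a polynomial intensity-dependent bias in the
  intervention channel; logistic dropout with midpoint Cq 38 and
  scale 0.5.
* `simulate_transcripts()`: i.i.d. uniform nucleotide background,
  5'UTR/CDS/3'UTR layout 15/55/30%, planted sites with exact
  controlled mismatch counts, overlap-protected and re-verified after
  planting.
* `simulate_cohort()`: 41 pairs in cells 11/9/10/11
  (Con-F/Con-M/N3-F/N3-M), log-normal amino acids (sdlog 0.3) around
  supplied medians -- consistent with levels skewed enough to warrant
  log transformation -- expression delta-Cq values with planted
  cell-mean shifts, outcomes from stated betas, and Bernoulli
  breastfeeding. A planted Con-M shift of $-0.87$ cycles
  ($\approx 1.83$-fold) reproduces the magnitude of reported
  sex-dimorphic expression differences as a recovery scenario.

These emulations are deliberately coarse. Real arrays have
assay-specific efficiencies, shared-pool correlation and C19MC-style
abundance clusters; real transcripts have composition bias and repeat
structure; real cohorts have correlated covariates and informative
missingness. Passing tests therefore demonstrate that the *methods*
are implemented correctly and behave nominally under their stated
assumptions -- not that the biological conclusions of any particular
study would replicate.

# Numerical choices and problem sizes

Tolerances: quantile-fit optimality is asserted to $10^{-8}$ against
the enumeration oracle; curve-tie classification uses $10^{-8}$;
exact p-values are compared to oracles at $10^{-12}$; calibrator
identities at $10^{-12}$. Percentages print half-up to one decimal.
The test suite uses 200 null arrays of 667 assays for cutoff
calibration, 1,000 random transcripts up to 1 kb for the seed-scan
oracle, and 500 replicates at n = 41 for the interaction type-I error
and CI-coverage checks; these sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping a full run in the
low minutes on one core.

# Known limitations

* One pool per group by design: no replicate-aware testing, no
  pre-amplification bias model.
* The binding score is a stand-in, not a reimplementation of any
  external prediction server; published enrichment p-values that
  depend on server-side scores are not reproducible here.
* No thermodynamic duplex energy, conservation filtering, or
  genome-coordinate mapping in the seed scanner.
* Association models are plain OLS -- no robust standard errors,
  mixed models, or mediation.
* The orchestrator (`run_pipeline()`) targets reproducible simulated
  or file-based runs, not workflow-engine integration.
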