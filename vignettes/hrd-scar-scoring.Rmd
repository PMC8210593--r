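---
title: "Genomic scar scoring and HRD biomarker analysis with hrdscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar scoring and HRD biomarker analysis with hrdscar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscar)
```

## The model

Tumors that cannot repair DNA double-strand breaks by homologous
recombination (HR) accumulate characteristic structural damage. Three
copy-number "scar" statistics, each computed from allele-specific
copy-number segments, quantify that damage:

* **LOH** — the number of loss-of-heterozygosity regions (minor allele copy
  number 0, major at least 1) longer than 15 Mb but shorter than the whole
  chromosome. Whole-chromosome LOH is excluded because it arises from
  mitotic missegregation rather than HR failure.
* **TAI** — telomeric allelic imbalance: the number of regions with unequal
  allele copy numbers that extend to a chromosome end but do not cross the
  centromere.
* **LST** — large-scale state transitions: the number of chromosome
  breakpoints (changes in copy number or allelic content) between adjacent
  regions of at least 10 Mb each, evaluated per chromosome arm after
  smoothing away copy-number variation shorter than 3 Mb.

The **HRD score** is the sum LOH + TAI + LST; a sample is HRD-positive when
the score is strictly greater than 26 (a score of exactly 26 is negative).
Downstream, the package stratifies a cohort into the bottom and top 20% by
HRD score, screens for differentially expressed genes between those groups
with a four-filter cascade (fold change > 1.5, BH-adjusted p < 0.05, mean
TPM > 1, top 75% of genes by median absolute deviation), and links candidate
genes — in the motivating application, interferon-induced chemokines such as
*CXCL10* downstream of cGAS–STING — to survival (Kaplan–Meier and log-rank),
discrimination (ROC/AUC), correlation (Pearson/Spearman) and categorical
response statistics (Fisher 2×2, Kruskal–Wallis).

## Segment model and smoothing

Internally all coordinates are 0-based half-open, so lengths are plain
differences; the common 1-based inclusive seg-file dialect is converted on
input (`read_segments(..., coords = "onebased")`, the default). Profiles may
contain gaps; uncovered regions carry no state.

Smoothing (`smooth_profile`, default scale 3 Mb) iterates to a fixpoint:
segments shorter than the scale are dropped; adjacent segments with an
identical (major, minor) state that abut directly or are separated only by
dropped segments merge, absorbing the dropped interval. Two deliberate
choices here:

* A dropped interval whose flanks *differ* in state remains a gap — only
  equal-state flanks absorb it. This is the conservative reading of
  "smoothing": it never invents a state for a region that had a different
  one.
* Abutting rows with an identical state are first merged ("canonicalized"),
  so a region split across several input rows is never dropped piecewise.
  This makes the operation agree with a per-base-pair definition of
  "region", which is also how the test oracles are written.

Smoothing is idempotent, and after it no segment is shorter than the scale
and no two abutting segments share a state.

## Counter conventions

Where the published scar definitions are silent, the package fixes a
convention and exposes it as a parameter:

* LOH regions are maximal runs of abutting LOH segments even when the major
  copy number changes inside the run (1/0 next to 2/0 is one region);
  `merge_runs = FALSE` switches to per-state runs. The length threshold is
  strict (`> 15 Mb`), and "shorter than whole chromosome" is evaluated
  against the geometry with a telomere tolerance (default 0 bp).
* TAI runs are defined by contiguity of the *imbalanced state*: any abutting
  imbalanced segments form one run regardless of the specific (major,
  minor) pair (`state_level = FALSE` switches to per-state runs). No minimum
  length is imposed by default (`tai_min = 0`), and "extends to the
  sub-telomere" means the run boundary lies within `tel_tol` (default 1 kb)
  of position 0 or the chromosome length, since "sub-telomere" has no
  universal coordinates.
* LST breakpoints are counted per arm: segments are truncated at the
  centromere interval and breakpoints inside it never count. "Adjacent"
  regions may be separated by a gap up to the 3 Mb filter scale, matching
  the smoothing allowance; the 10 Mb flank minimum is inclusive.
* No ploidy or tumor-purity correction is applied anywhere. Some published
  LST variants subtract a ploidy penalty; the definitions implemented here
  do not, and the documentation flags this rather than guessing.

## The DEG cascade

TPM is computed as reads per base of transcript, rescaled per sample to one
million. The differential test between the extreme HRD quintiles is a Welch
t-test on log2(TPM + 1) with the fold change computed on mean TPM with a
pseudocount of 1. This is a deliberate stand-in: the motivating analysis
used a negative-binomial count model (edgeR), but mandating an external
package would break self-containment, and the package's specified
computation is the *filter cascade*, not the test. A precomputed
(gene, log2FC, p) table from any external tool can be ingested via
`deg_cascade(..., de_table = )`.

Two threshold ambiguities are resolved as follows and kept configurable:
"fold change > 1.5" is interpreted on the natural scale (|log2FC| >
log2 1.5 ≈ 0.585), not as |log2FC| > 1.5; "TPM > 1" is evaluated on the mean
across all cohort samples, not per group. Multiple testing uses
Benjamini–Hochberg (the source analysis says only "adjusted p"/"FDR"). MAD
is computed on log2(TPM + 1) without the 1.4826 consistency constant — the
ranking, which is all the filter uses, is unaffected.

## Statistics

The survival, correlation and categorical statistics are implemented
in-package (product-limit estimator; O−E/V log-rank for k groups;
empirical ROC with trapezoid AUC, which equals the Mann–Whitney identity
with ties counted half; Pearson/Spearman with t-approximation p-values;
two-sided Fisher by the probability-mass rule; tie-corrected
Kruskal–Wallis). This keeps the dual-route tests meaningful: every routine
is checked against an independent oracle (`survival::survfit`/`survdiff`,
`p.adjust`, `wilcox.test`, `fisher.test`, `kruskal.test`, or hand
computation) to 1e-12 on statistics and 1e-9 on p-values.

Group comparisons between independent samples use the Wilcoxon *rank-sum*
(Mann–Whitney) test — exact enumeration for pooled sizes up to 12, otherwise
a tie-corrected normal approximation without continuity correction. The
motivating figures label this comparison "Wilcoxon signed-rank", but the
groups there are independent patients, so the rank-sum test is what the
analysis can actually mean; this is documented rather than silently
replicated.

The expression high/low split for survival is a median split (values
strictly above the median are "high", so with odd n the median observation
is "low"). No published cut point exists for this choice; an optional
best-cutoff mode scans inner quantiles for the split maximising the log-rank
statistic, and warns that the resulting p-value is optimistic because the
cut is chosen on the same data.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` produce segment profiles, an expression
matrix and clinical outcomes with the statistical structure the analysis
assumes, so every pipeline stage is testable without external downloads.

**Genome.** Three chromosomes of 100/150/200 Mb with centromeres at 40–45,
60–65 and 95–100 Mb — about 15% of a human genome, small enough that test
oracles can scan per-megabase state vectors.

**Scar events.** Per sample, event counts are drawn from Poisson
distributions (defaults λ_LOH = 2, λ_TAI = 1.5, λ_LST = 2, i.e. typical
HRD-tumor scar burdens scaled to the toy genome's size) and planted
disjointly on a diploid 1/1 background: interstitial 1/0 LOH runs of
15–40 Mb, telomere-anchored 2/1 imbalance runs of 10–25 Mb, and 2/1|3/1
breakpoint pairs with 10–15 Mb flanks. Every event is isolated by 4 Mb
balanced (2/2) buffer segments — longer than the 3 Mb smoothing scale,
shorter than the 10 Mb LST flank minimum — so each planted event registers
in exactly one scar class and the counters recover the planted counts
*exactly*, enabling exact rather than approximate recovery tests. Positions
are drawn uniformly over the free space that can host the event; a draw
whose counts cannot be arranged at all is redrawn, so the realized counts
are Poisson conditioned on joint placeability (a distortion of a few
percent of the mean at default rates; the error "geometry too small" is
raised only when no draw can be placed). Event sizes are capped well below
a whole chromosome both for realism and so the default rates fit the
genome.

**Expression.** Six chemokine-like "responsive" genes follow
log2 TPM = 5 + β·HRD + N(0, σ) with β = 0.15 and σ = 0.5; the remaining
genes (200 total by default) get baselines uniform on log2 TPM −10..10, so a
realistic minority falls below the TPM > 1 filter. Columns are rescaled to
sum to 1e6. At these defaults the Spearman correlation between a responsive
gene and the HRD score is ≈ 0.5 at n = 200, comfortably above the 0.4
association strength the design targets, and the extreme HRD quintiles
differ by about 0.9 log2 units — above the fold-change filter with a large
t-statistic margin.

**Clinical.** Survival is exponential with hazard h0·exp(γ) for the
expression-high half (median split of the first responsive gene), h0
otherwise; defaults h0 = 0.05/month and γ = −1.1 (hazard ratio ≈ 1/3).
Censoring is independent: each subject is censored with the target
probability at a uniform time before its event, which hits the censoring
rate exactly in expectation. Instability covariates rise with the true HRD
score — Poisson mutation counts (10 + 3·HRD), a logistic-scale fraction
genome altered (slope 0.25/point) and a gamma-noise MSI-like score (slope
0.5/point) — with slopes sized so the extreme quintiles of an n = 100
cohort separate by roughly three noise standard deviations, giving the
rank-sum comparison ≥ 90% power at α = 10⁻⁴. Response categories
(CR/PR/SD/PD) are multinomial with expression-group-dependent
probabilities (40% vs 10% CR+PR).

**What a green test does and does not establish.** The generator plants
clean, isolated events on an exact integer-CN background. It deliberately
omits segmentation noise, fractional copy numbers, subclonality,
tumor-purity and ploidy confounding, and correlated gene–gene expression
structure. Green tests therefore establish that the *counting and
statistical machinery* is correct under its stated definitions — not that
the pipeline is robust to noisy real-world segmentations.

## Numerical and degenerate-input choices

* Thresholds: LOH length strict (> 15 Mb), LST flanks inclusive (≥ 10 Mb),
  LST gap ≤ 3 Mb, HRD positivity strict (> 26).
* Rank-sum with all values identical, Kruskal–Wallis with all values
  identical, and a differential test on a gene with zero variance in both
  groups all return p = 1 with a warning rather than failing.
* Correlation with a zero-variance vector is flagged `degenerate = TRUE`
  with an NA estimate.
* KM ties: events precede censorings at equal times.
* Stratification uses floor(fraction·N) per group with ties broken by
  sample id, so results are invariant under input permutation.
* Determinism: every simulator substream is derived from the single config
  seed (per sample and per stage), so identical configs reproduce
  byte-identical pipeline outputs; the run manifest records md5 checksums
  of every input and output file.

## Known limitations

* The LST definition's ambiguities (genome-wide vs per-arm counting, ploidy
  correction) are resolved per the original per-arm source definition and
  documented; other choices would shift absolute scores.
* The built-in differential test is a Welch stand-in, not a count model;
  with few samples per group a negative-binomial model has better power.
  Use the ingestion path for serious count data.
* The HRD > 26 threshold is taken as given; no attempt is made to
  re-derive or recalibrate it, and scores from this package on real data
  should be recalibrated before clinical interpretation.
* Sex chromosomes receive no special ploidy handling; profiles are used as
  given.
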