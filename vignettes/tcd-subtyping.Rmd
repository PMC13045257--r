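---
title: "T cell dysfunction profiling and consensus subtyping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{T cell dysfunction profiling and consensus subtyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TCDtype)
```

## The model

TCDtype quantifies, for every tumour sample, how strongly four T cell
dysfunction (TCD) states — exhaustion, senescence, exclusion and
dysfunction — are engaged, and derives severity-ordered tumour subtypes and
downstream prognostic models from that profile.

### Per-sample enrichment (the TCD profile)

For a tumour sample, each gene's fold change is its expression divided by the
average expression of the normal reference samples (plus a small pseudocount,
default 0.01, because FPKM zeros occur). Genes with FC > 2 or FC < 0.5
(strict) are that sample's differentially expressed genes (DEGs). Each TCD
signature is then tested for over-representation of the sample's DEGs with a
hypergeometric test: with `N` genes in the universe, `M` DEGs, `n` signature
genes in the universe and `k` DEGs in the signature, the probability of an
overlap of exactly `k` is

$$P(k; N, M, n) = \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},$$

and the profile entry is the upper tail $P(X \ge k)$ — the point mass alone
is not a test, so the enrichment p-value sums the tail. The profile is the
4 × samples matrix of these p-values. Computation is in log space via
`lchoose`, so large universes do not overflow.

Numerical choices worth knowing:

* The gene universe is every gene whose normal mean plus pseudocount is
  positive (all genes for any positive pseudocount). Signature members
  absent from the universe are dropped from `n`, keeping `k <= n`.
* Strongly enriched samples underflow raw p-values to 0. The profile
  therefore carries a companion `-log10(p)` view capped at 300, and
  **clustering uses the `-log10` view by default**: on the raw p scale all
  strongly enriched samples collapse onto identical all-zero profiles, so
  distances can no longer rank severity among them. Raw-p clustering remains
  available (`transform = "p"`).

### Consensus subtyping

The profile is clustered by consensus: 100 subsampling draws of 80% of the
samples (the conventional defaults of the consensus-clustering approach),
each clustered by partitioning around medoids (PAM) under Manhattan
distance, for k = 2..8. The consensus entry for a sample pair is the
fraction of co-draws in which they co-clustered. Per k, the area under the
empirical CDF of consensus values is computed exactly as
`1 - mean(consensus)`; the relative delta-area sequence
$(A_k - A_{k-1})/A_{k-1}$ selects k as the smallest k whose successor's
delta-area first drops below 0.1 (configurable). Final labels come from PAM
on `1 - consensus`.

PAM here is deterministic: ties break to the lowest index everywhere. When
the medoid search space is small (`choose(n, k) <= 2000`) the implementation
enumerates every medoid set and returns the optimum — textbook BUILD+SWAP is
only locally optimal and measurably misses the optimum on a few percent of
small instances, which would make results depend on the accident of the
starting medoids. Beyond that bound the classic greedy BUILD seeding plus
steepest-descent SWAP is used.

Clusters are ordered by their mean `-log10(p)` over the four states — the
severity ordering is not part of the clustering itself, so the package makes
the ordering rule explicit — and named T-low, T-middle, T-middle2, T-high
at k = 4 (analogous low/middle/high names at other k).

### Downstream analyses

* **Signature scores** — mean of per-gene z-scores over set members
  (population SD, ddof 0, a fixed documented convention), or a rank-based
  variant (`rank-z`) that first converts each sample to within-sample gene
  ranks scaled to (0, 1], making scores invariant to monotone per-sample
  transforms. These are deliberately simple, documented replacements for
  kernel-based single-sample enrichment scores; the method tag travels with
  the output.
* **Differential features** — Welch's t-test per feature on `log2(x + 1)`
  for expression (raw scale for beta values), with Benjamini–Hochberg
  adjustment. Moderated-variance statistics are intentionally not used: the
  Welch test is self-contained and calibrated, and the selection thresholds
  (|log2FC| > 1 with p < 0.01 for miRNAs; delta-beta > 0.15 with FDR < 0.05
  for methylation probes, all strict) transfer directly. Multi-subtype
  contrasts default to one-vs-rest with the subtype of interest as group A.
* **Survival** — Kaplan–Meier estimation and log-rank tests delegate to the
  survival package. The Cox proportional-hazards fit is the package's own
  Newton–Raphson maximiser of the Breslow partial likelihood (convergence
  when the largest score component is below 1e-8, at most 50 iterations,
  step-halving, covariates centred for stability); standard errors come from
  the inverse observed information. Breslow tie handling keeps the
  likelihood simple enough to verify against a brute-force grid, which the
  test suite does, alongside agreement with `survival::coxph(ties =
  "breslow")`. The linear risk score is f(X) = x'beta; samples at or above
  the median score are high-risk (ties go to high-risk, documented), below
  it low-risk. External validation freezes the coefficients and re-applies
  score + median split, never refitting.
* **Classifiers** — random forests (500 trees) over small miRNA panels,
  evaluated threshold-free by AUC; AUC is computed by the exact
  Mann–Whitney rank formula with ties half-counted. Splits (70/30 by
  default, 60/20/20 supported) use largest-remainder allocation after a
  seeded shuffle, stratified on request.

## The synthetic cohort generator

Every stage is tested against cohorts with planted ground truth, generated
by `generate_cohort()`:

* **Expression** — log-normal: log2 values are N(5, sd) per gene and sample,
  exponentiated to FPKM-like positives. Subtype s (severity grades 0..3)
  shifts signature genes by `severity_effects[s]` log2 units (default
  0/0.5/1/2). The default within-gene dispersion is `noise_sd = 0.5` on the
  log2 scale (~41% CV). This is a deliberate calibration: the FC > 2 /
  FC < 0.5 rule thresholds sit asymmetrically around the log-normal
  arithmetic mean (the Jensen offset is $\sigma^2 \ln 2 / 2$ log2 units), so
  at a dispersion of 1.0 log2 an up-shift of 0.5 mostly converts
  down-calls into non-calls and the profile becomes blind to the weakest
  planted subtype — with replicate scatter of 0.5 log2, typical of
  within-tissue FPKM variability, a 0.5 log2 shift is detectable and planted
  enrichment is monotone in severity, which is the structure the analysis
  assumes.
* **miRNAs** — same model; by default six informative miRNAs among nulls,
  three rising 0.75 log2 per severity grade (the T-high panel) and three
  falling (the T-low panel), so one-vs-rest extreme contrasts plant
  |log2FC| = 1.5.
* **Methylation** — logit-normal beta values (respecting the (0, 1)
  support); a block of 40 probes loses 0.5 logit units of mean per severity
  grade, giving extreme-subtype delta-beta ≈ 0.35.
* **Targets** — ten non-signature genes fall 0.75 log2 per grade and are
  listed as candidate targets of the first T-high-panel miRNA, together with
  positively-correlated signature decoys, so the anti-correlation filter has
  a known answer.
* **Survival** — exponential event times with log-hazard
  `log(0.1) + grade * 1.0`; censoring is an independent uniform time whose
  upper bound is calibrated in closed form per subject so the expected
  censored fraction is exactly `censor_fraction` (default 0.3).
* One random stream is seeded once per cohort; sub-generators draw child
  seeds from it, so cohorts are byte-identical functions of their
  configuration.

What the generator does **not** emulate: batch structure, cancer-type
composition, gene–gene correlation beyond the planted effects, count-based
mean–variance relationships, or real miRNA–target biology. Passing tests
demonstrate that the pipeline recovers structure it is pointed at, under its
own assumptions — not that those assumptions hold in any particular real
cohort.

## Problem sizes used in the checks

The test suite and the acceptance script run the cohort at its default size
(four subtypes × 50 tumour samples, 50 normals, 2000 genes, 100 consensus
resamples) for subtype recovery, and scale supporting simulations to sizes
where the targeted property is already well resolved: 50 replicates of
n = 1000 for Cox recovery, 500 null replicates for log-rank calibration,
2000 features for the Welch null, 200 random instances for the PAM oracle,
and full enumeration up to N = 12 for the hypergeometric oracle.

## Known limitations

* The hypergeometric profile conditions on the per-sample DEG count; samples
  with very few DEGs have granular p-values, and the four states are tested
  marginally (overlapping signatures are not deconvolved).
* The delta-area rule inherits the usual consensus-clustering bias toward
  visually "clean" k; the full delta-area sequence is always reported so the
  choice can be audited.
* The Cox fitter targets small covariate panels (the intended use); it does
  not implement Efron ties, stratification, or time-dependent covariates,
  and the baseline hazard is not estimated (risk ranking needs only x'beta).
* One-vs-rest differential contrasts do not adjust for the remaining
  subtype mixture; an extreme-vs-extreme contrast can be run by passing the
  two extreme groups directly.
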