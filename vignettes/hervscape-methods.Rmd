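---
title: "Quantifying endogenous retrovirus expression with a virus metagenome: methods and design"
author: "hervscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endogenous retrovirus expression with a virus metagenome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervscape)
```

## Scope and model

hervscape implements a virus-focused expression workflow for bulk RNA-seq of
cell lines undergoing a microenvironmental perturbation (here: a switch from
serum-supplemented to serum-free stem-cell medium), together with qPCR
relative quantification and a correlation-based gene screen anchored on a
HERV transcript. All inputs can be simulated in-package with known ground
truth, which is how the test suite exercises every stage.

### The virus metagenome

The reference is not a genome but a curated collection of elements, each
with an id, an accession-style label, a family and a category:

* `endogenous_human` — HERV elements of named families plus bornavirus-like
  EBLN elements;
* `housekeeping` — control transcripts (HPRT1, ACTB, GAPDH, TUBB);
* `spacer` — sequences of unrelated viruses whose only role is to absorb
  reads that would otherwise be forced onto an endogenous element, which
  sharpens the uniqueness call.

The packaged default (`make_default_manifest`) reproduces the published
composition — 119 endogenous human viral elements of which 115 are HERV
elements over 14 families (92 full-length HERV-K(HML-2)) and 3 are EBLN,
plus 4 housekeeping and 124 spacer elements — but its sequences are
pseudo-random; no real accession is shipped or fetched. Two bookkeeping
choices are worth making explicit. First, the published counts leave one of
the 119 endogenous elements unaccounted for (115 HERV + 3 EBLN = 118), so
the default manifest carries one explicitly *unclassified* endogenous
element rather than inventing a family for it. Second, only a handful of
family names are fixed by the source material (HERV-K(HML-2), HERV-W,
HERV-Fc, HERV-R(ERV3), HERV-E, EBLN); the remaining family labels and their
sizes are plausible placeholders, chosen once. Element lengths are drawn
uniformly from 1,000–9,500 bp, the range typical of near-full-length
proviral sequences and their subregions.

### Unique fragment assignment

The quantification rule is: count a read pair for an element only when it
maps there *uniquely*. Since the package targets desk-scale synthetic data,
it ships its own gapless matcher rather than wrapping an external aligner:

1. k-mer seeds (default `k = 31`) taken from the prefix and suffix of each
   mate in both orientations are located exactly on the forward strands of
   all elements with an Aho–Corasick dictionary scan;
2. every candidate placement is verified by a full gapless comparison of
   the mate against the element (per-mate mismatch budget, default 2);
3. a pair is *consistent* on an element when the two mates match on
   opposite strands in inward orientation with a fragment span of at most
   `max_frag` (default 1,000 bp);
4. the fragment is credited to the element with the lowest total mismatch
   count; an equal-best tie across elements is counted as **ambiguous** and
   credited to nothing; a fragment with no consistent placement is
   **unassigned**. `sum(unique) + ambiguous + unassigned = total` always
   holds.

This "unique best score, ties discarded" contract is an explicit stand-in
for MAPQ-based unique-read filtering in short-read aligners; indels are not
modelled because the read simulator emits none. The test suite pins the
contract against an independent exhaustive-scan oracle on dozens of random
scenarios, including scenarios with verbatim segments copied between
elements so that some fragments are genuinely ambiguous by construction.

### FPKM, element- and family-level

For element $i$ with $c_i$ assigned fragments and length $L_i$ bp,

$$\mathrm{FPKM}_i = \frac{c_i \times 10^9}{L_i \times N},$$

where $N$ is the total number of fragments uniquely assigned to the
metagenome (per sample). Using the within-metagenome total rather than the
whole-library total is a deliberate choice — the whole-library total is not
observable from the assignment result; it scales all absolute values by a
constant per sample and cancels from fold changes as long as the features
of interest are a small fraction of assigned reads (see *Numerical
choices*). The family value treats the family as one merged pseudo-element:

$$\mathrm{FPKM}_F = \frac{\left(\sum_{i \in F} c_i\right) \times 10^9}
{\left(\sum_{i \in F} L_i\right) \times N}.$$

This is *not* the mean of member FPKMs when member lengths differ; a
regression test pins the distinction with a counter-example. Spacer and
housekeeping "families" are excluded from family tables by default.

### Median-calibrated 2^−ΔΔCt

Technical replicates are collapsed by the arithmetic mean of Ct per
(sample, gene); then $\Delta Ct = \overline{Ct}_{target} -
\overline{Ct}_{reference}$ per sample (reference gene: HPRT1). The
calibrator sets the per-gene **median of all samples to 1**:

$$\mathrm{rel} = \frac{2^{-\Delta Ct}}{\operatorname{median}(2^{-\Delta Ct})}
= 2^{-(\Delta Ct - c)}, \qquad c = -\log_2 \operatorname{median}(2^{-\Delta Ct}).$$

The calibrator is defined on the linear $2^{-\Delta Ct}$ scale rather than
as the median ΔCt. For an odd number of samples the two are identical; for
an even number the midpoint-on-ΔCt convention would make the median
relative expression $\tfrac12(2^{\delta} + 2^{-\delta}) \ge 1$, breaking
the "median = 1" guarantee, so the linear-scale definition is used for all
sample counts and the guarantee holds exactly (tested at 1e-12).
Amplification efficiency is fixed at 2 (the doubling assumption behind
2^−ΔΔCt); Pfaffl-style efficiency correction is out of scope.

### Group statistics

Per gene, a balanced fixed-effects two-way ANOVA with interaction is fitted
on $\log_2(\mathrm{rel})$ — the log scale stabilizes the variance of
fold-change data; the raw scale is available via `response_transform =
identity`. Unbalanced designs are rejected outright rather than silently
switching between sum-of-squares types. Tukey HSD comparisons are computed
within strata (media within each cell line by default), using the pooled
residual mean square and error degrees of freedom of the full model and
studentized-range p-values; significance tiers are reported as `**`
(p < 0.01), `***` (p < 0.001), `****` (p < 0.0001), with `*` at 0.05 also
shown. The factor pairing (cell line × medium per gene) is the default and
both factors are arguments, since the alternative stratification is equally
defensible.

### The anchor screen

The screen pairs an RNA-seq expression matrix with a condition-level qPCR
anchor (anchor values are measured per cell line × medium and replicated
across the RNA-seq samples of that condition; the qPCR and RNA-seq
replicate counts need not match). A gene passes when

* $|r| \ge 0.7$, where $r$ is the Pearson correlation between the gene's
  per-sample expression and the anchor vector across **all** samples of all
  cell lines jointly, and
* its fold change between serum-free and serum-supplemented groups (the
  two serum-containing media pooled) is $\ge 1.4$, computed on group means
  with a pseudocount (default 0.01 FPKM) guarding zeros and expressed
  $\ge 1$ with a separate direction.

Direction (up/down) follows the fold change; the signed correlation is
reported alongside, since the two can disagree in principle. Constant genes
are excluded and counted — they are never assigned $r = 0$. Correlation is
computed on untransformed expression by default (`log2_expr = TRUE`
optional). Row Z-scores, $(x - \bar x)/s$ with the $n-1$ denominator, are
produced for heatmap display, and families are ranked by the signed log2
serum-free differential of their family FPKM.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` (seed length) | 31 | bp | long enough that random 31-mer collisions are negligible; shorter than any read |
| `max_mismatches` | 2 | per mate | tolerates the simulator's substitution errors at 150 bp reads |
| `max_frag` | 1000 | bp | upper bound on insert size for a consistent pair |
| `frag_len` / `read_len` | 250 / 150 | bp | fixed fragment length; enough inner distance to exercise pairing |
| NB dispersion | 0.02 | — | clonal cell-line replicates are low-dispersion; variance = μ + 0.02 μ² |
| `noise_sd` (qPCR) | 0.25 | cycles | typical well-to-well SD for SYBR assays |
| `r_threshold` / `fc_threshold` | 0.7 / 1.4 | — | the published screen thresholds |
| `pseudocount` | 0.01 | FPKM | keeps zero-expression fold changes finite without visibly distorting expressed genes |

## What the simulators emulate — and what they do not

`simulate_counts` draws negative-binomial fragment counts with planted
multiplicative serum-free effects per feature and cell line (the source
material states no noise model; NB is the standard bulk RNA-seq
assumption). `simulate_reads` places fixed-length fragments uniformly along
elements, optionally after copying verbatim segments between elements so
that reads from the copied region are ambiguous by construction; errors are
uniform substitutions, qualities constant. `simulate_ct` inverts the
doubling model: $Ct_{target} = Ct_{ref,base} - \log_2(\text{level}) +
\varepsilon$. Each generator is deterministic under its seed and returns a
ground-truth sidecar.

Passing tests on these inputs demonstrate that the *computations* are
correct and that planted signals of realistic size survive the full path;
they do not demonstrate robustness to features of real data that are
deliberately not modelled — indels and quality-dependent errors,
non-uniform coverage, splicing, GC bias, unbalanced designs, or the
reference-choice uncertainty of real HERV annotation. The published
real-data findings (e.g. the specific 198-gene list or any particular
correlation value) require the original raw reads and a human-genome
alignment, and are intentionally out of scope.

## Numerical choices and degenerate inputs

* **Ties in assignment** are ambiguous, never arbitrarily broken.
* **FPKM denominator sensitivity**: because $N$ is the within-metagenome
  total, a planted effect on features carrying a large share of the
  library shifts $N$ itself and compresses recovered fold changes. The
  recovery checks therefore plant effects on a family contributing only a
  few percent of assigned fragments (a 4-member family in a 100-element
  reference), matching the regime the method is used in — HERV families
  against a 247-element metagenome. At that share the residual compression
  is below 4%, well inside the acceptance band; at a 20% share it reaches
  ~20% and the band would be missed for reasons unrelated to correctness.
* **Constant responses** in ANOVA give zero residual variance; F and p are
  reported as `NA`, not fabricated. Identical Tukey groups report q = 0,
  p = 1.
* **Missing qPCR wells** are dropped with a warning; a sample missing the
  reference gene is an error naming the sample.
* **Even sample counts** in the median calibration are handled exactly by
  the linear-scale calibrator (see above).
* **Problem sizes** used by the checks: 50 random assignment scenarios of
  3–8 elements × ~100 fragments against the exhaustive oracle; 2,000 null
  simulations for the ANOVA type-I calibration; a 530-gene × 18-sample
  screen; the full 247-element scenario for the end-to-end determinism
  check. These sizes give stable statistics while keeping the default test
  run fast.
* **Randomness**: every generator takes an explicit seed; the pipeline
  derives one substream per stage from the master seed and the stage name,
  so enabling or disabling a stage never changes another stage's draws.

## Known limitations

* The matcher is gapless and seed-based: a placement whose prefix *and*
  suffix 31-mers are both corrupted by errors is missed. At the default
  error rate this is rare; at high error rates the assigner under-counts
  relative to a full aligner.
* Family-level FPKM inherits the usual caveat of length-weighted pooling:
  a family dominated by one long, silent member dilutes the signal of a
  short, active one. This is the published aggregation rule, reproduced
  faithfully rather than "improved".
* The screen's two filters are marginal (no joint null model, no multiple
  testing correction) — again by design, as a reproduction of the
  published selection procedure, not a replacement for differential
  expression modelling.
* qPCR quantification assumes perfect doubling; no standard curves.
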