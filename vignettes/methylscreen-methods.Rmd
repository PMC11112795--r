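---
title: "Methods: DMR calling and methylation-expression integration in small tumor/normal WGBS designs"
author: "methylscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling and methylation-expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

## Scope and model

`methylscreen` implements the analysis chain of a small paired
tumor/normal whole-genome bisulfite sequencing (WGBS) study — typically
three tumor and three adjacent-normal tissues — coupled to RNA-seq from
the same samples. The package covers five stages:

1. **Per-cytosine summarization.** The methylation level of a cytosine
   is the fraction of reads reporting it methylated,
   $R_m = N_m / (N_m + N_{nm})$, where $N_m$ and $N_{nm}$ are the
   methylated and unmethylated read counts. Cytosines are classified by
   sequence context (CG, CHG, CHH; H = A/C/T); in human tissue CG
   carries essentially all methylation and CHG/CHH sit near 1%.
   Sample-level reports give the per-context composition of methylated
   cytosines and group rows as mean ± sample (n−1) standard deviation.
2. **DMR calling.** A differentially methylated region is a run of at
   least 5 CG-context cytosines whose *pooled* group levels differ by
   more than 2-fold with P < 0.05 (both strict).
3. **DEG screening.** A gene is downregulated when its log2 fold change
   (tumor over normal) is ≤ −1 with P < 0.05, upregulated at ≥ 1
   (thresholds inclusive).
4. **Crossover integration.** Genes carrying a hypermethylated DMR and
   a downregulated label form the candidate methylation-silenced
   tumor-suppressor set (`hyper_down`); hypomethylated × upregulated
   forms the mirror set. A Spearman co-expression screen
   (|rho| ≥ 0.3) and uncorrected Pearson chi-square tests on 2×2
   clinical tables support downstream interpretation.
5. **Demethylation response.** For a MassArray-style CpG-unit panel
   measured before and after 5-azacytidine, the response of a unit is
   its *relative* decrease, $(L_{before}-L_{after})/L_{before}\times
   100\%$, and the panel readout is the unit with the largest relative
   decrease.

## The DMR procedure in detail

The criterion above fixes what a DMR *is* but not how candidate regions
are found, which test produces P, or how a small-replicate design is
pooled. Those were open design choices; the package resolves them as
follows.

**Usable sites.** A site is usable when it is CG context and covered by
at least `min_coverage` (default 4) reads in *every* sample of both
groups. Plus- and minus-strand CpG records are kept distinct; an
optional destranding merge is deliberately not the default because both
conventions are common in practice.

**Candidates.** Sliding windows of `window_cpgs = 5` consecutive usable
CpGs (step one site) are the candidate regions, rejected when any
consecutive gap exceeds `max_gap = 300` bp. Five is the smallest width
the criterion admits, so windowing at 5 with union (below) can discover
every region the criterion could accept; deterministic windows also
admit an exhaustive-enumeration oracle in the test suite.

**Test.** Counts are pooled within group over the region's sites —
level $= \sum N_m / \sum(N_m+N_{nm})$ — and P comes from a two-sided
Fisher exact test on the pooled 2×2 table (methylated/unmethylated ×
tumor/normal). At three replicates per group, per-sample region levels
give the significance test almost no degrees of freedom, whereas pooled
counts admit an exact test with a closed-form hypergeometric oracle.
The documented cost is anti-conservatism under biological
overdispersion: pooling treats reads as the unit of replication. The
calibration tests therefore run at `overdispersion_rho = 0`, where the
pooled table is exactly hypergeometric under the null; on real tissue
the P values should be read as a ranking device inside a fold-change
gate, which is how the thresholded criterion uses them.

**Fold.** The fold is computed on regularized levels,
$(\max(L_t,L_n)+\varepsilon)/(\min(L_t,L_n)+\varepsilon)$ with
$\varepsilon = 0.01$, so fully unmethylated regions have a finite fold.
A fold of exactly 2 is rejected ("more than 2-fold").

**Union and merge.** Overlapping significant windows of one direction
are unioned into maximal regions; each union is re-tested over *all*
usable CpGs it contains and kept only if it still meets the criterion.
A second pass merges *adjacent* same-direction regions: the span from
the start of one to the end of the next is evaluated over every usable
CpG inside (not only the two regions' own sites), and the pair is
replaced when the span itself qualifies. The scan iterates to a
fixpoint, which makes the merge idempotent; opposite-direction
neighbours never merge. There is no distance cap on merging — the span
test itself is the guard, since intervening background CpGs dilute the
pooled signal.

Multiple-testing correction across windows is deliberately absent: the
screen is threshold-based, and the planted-recovery and null
simulations quantify its operating characteristics instead.

## The DEG screen

Counts are normalized to counts per million (CPM); the log2 fold change
is computed on group mean CPM with a pseudo-count of 1, and P from a
two-sided Welch t-test on log2(CPM+1). At n = 3 vs 3 this is the
simplest defensible test; moderated-variance methods would gain power
but add no clarity to a thresholded screen. All-zero genes are neutral
with P = 1 and flagged rather than dropped.

## What the synthetic generator emulates — and what it does not

`sim_config()` defines a synthetic study: one chromosome, 3 + 3
samples, background CpGs at a common level (default 0.3), CHG/CHH
records at level 0.01 (matching the ~1% non-CG methylation of human
tissue), and planted DMRs anchored in the promoters of distinct genes
(8 CpGs spaced 100 bp apart by default, tumor 0.8 vs normal 0.2).
Coverage is Poisson (mean 30) truncated at 1 so every emitted site is
covered; methylated counts are beta-binomial with mean equal to the
site's true level and overdispersion `rho` (`a = mu(1−rho)/rho`,
`b = (1−mu)(1−rho)/rho`), degenerating to exact binomial at `rho = 0`
so calibration tests have closed-form oracles. Expression is negative
binomial (dispersion 0.1, a standard "moderate" value for bulk tissue
replicates) around log-normal baselines, and each promoter-hyper-DMR
gene is planted as a down-DEG with probability `coupling_prob`
(hypo → up symmetrically) at a planted |log2FC| of 2.

Design note: planted DEGs should stay a small fraction of all genes.
When a large share of genes shifts in one direction, CPM normalization
itself shifts every log2 fold change (a composition effect familiar
from RNA-seq normalization); the test and acceptance configurations
plant 30–50 coupled genes among 300–600, mirroring the few-percent DEG
fraction of real tumor/normal transcriptomes.

The generator intentionally omits several properties of real WGBS:
read-level sequences and bisulfite-conversion errors, CpG-island
spatial structure and distance-decaying correlation of methylation,
copy-number and purity effects in tumors, and mappability-driven
coverage bias. Passing recovery tests therefore demonstrates that the
implementation honours its own criterion and is well calibrated under
its sampling assumptions — not that the criterion is optimal on real
tissue.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale instances
chosen to make Monte-Carlo checks sharp while keeping runs in seconds:
10,000 sites for binomial calibration (3 standard-error bands), 2,000
dense CpGs for the null type-I rate, 50 planted DMRs across 600 genes
for sensitivity, and 30 planted DEGs across 300 genes for label
recovery. Reported tables round half away from zero (3 decimals for
percentages, 1 for relative decreases), matching the conventions of
published summary tables; raw values are kept alongside. Fisher P
values use R's exact implementation and are compared in tests against
an independent log-space hypergeometric enumeration. All randomness
flows from a single integer seed; identical configurations reproduce
byte-identical outputs.

Two further conventions resolve ambiguities a reader may notice.
Whole-genome summary tables report two different "mCG" quantities: the
*mean methylation level* of covered CG sites (typically 40–75% in human
tissue) and the *share of methylated cytosines* that are CG context
(typically 92–95%); the package computes both and labels them
distinctly. For the demethylation panel, "decrease" is relative, not
absolute — only the relative reading reproduces the conventional
percent-response figures — and the panel argmax is computed both over
all units and over a caller-selected subset, since assay panels often
include units that respond little and are excluded from headline
claims.

## Known limitations

- Pooled Fisher testing is anti-conservative under overdispersion;
  interpret P on real data through the fold-change gate, or extend
  `region_test()` with a beta-binomial likelihood-ratio test.
- The merge rule can bridge long spans when intervening CpGs are
  sparse but concordant; the span re-test is the only guard.
- The DEG screen's Welch test at n = 3 is low-powered; planted-label
  recovery of ~0.85–0.95 at |log2FC| = 2 and dispersion 0.1 is the
  realistic ceiling for this design, and weaker effects will be missed.
- Gene annotation handling assumes one transcript per gene with a
  single TSS; promoter windows are fixed (2 kb up, 0.5 kb down) rather
  than isoform-aware.
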