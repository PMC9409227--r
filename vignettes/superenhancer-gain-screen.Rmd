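---
title: "Super-enhancer gain discovery and prognostic screening: methods"
author: "segain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer gain discovery and prognostic screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segain)
```

# The analysis

`segain` implements a two-part analysis of drug-adaptation epigenomics.
The first part discovers *super-enhancers* (SEs) — large clusters of
H3K27ac-marked enhancers — from ChIP-seq fragment and peak input, and asks
which SEs are *gained* after long-term drug exposure in two independent
cell lines of the same tumor type. The second part takes the genes lying in
or near the common gained loci and screens them in a tumor/normal cohort
for prognostic value: upregulation in tumors, survival stratification,
alteration co-occurrence, and pathway enrichment.

The package is organised as an analysis workflow: every computational step
lives in the package (`R/`), the numbered scripts under `analysis/` are
thin narrative drivers, and a synthetic-data generator with planted ground
truth makes the full chain testable without any external download.

# Coverage model

Aligned fragments (BED6; the score column read as MAPQ) are processed with
three rules before any signal is computed:

* **Mapping quality.** Fragments with MAPQ of 25 or below are discarded;
  the threshold is strictly exclusive (26 is kept, 25 is not). Fragments
  with no MAPQ value are kept — synthetic or pre-filtered inputs often
  omit the column, and silently dropping them would be worse than
  documenting the pass-through loudly here.
* **Duplicates.** Fragments sharing (chromosome, 5' position, strand) are
  collapsed to one. The operation is idempotent.
* **Extension.** Each fragment is replaced by an interval of exactly
  200 bp anchored at its 5' end, clipped at coordinate 0. "Extended to a
  length of 200 bp" is read as *set to* 200 bp: short fragments grow and
  long ones are truncated, giving one deterministic rule instead of a
  length-conditional one.

Extended fragments are accumulated into 32-nt bins. A bin receives the
number of *bases* by which each fragment overlaps it (base-mass), not a
once-per-fragment count. Base-mass makes conservation exact — total track
mass equals the summed extended fragment lengths — which in turn makes the
coverage module testable against a per-base brute-force oracle. Whether
the original pipeline counted bases or midpoints per bin is not documented
anywhere we could find; base-mass is the choice that yields a checkable
invariant, and region quantification below is normalized, so ranking is
insensitive to the constant factor.

Chromosome lengths come from a chrom-sizes table when given, otherwise
from the largest observed coordinate rounded up to a bin boundary.

# Super-enhancer calling

Peak calls (narrowPeak/BED, 0-based half-open, taken as given — peak
calling itself is upstream of this package) are first cleared of entries
overlapping a blacklist of artifact regions by at least 1 bp.

**Stitching.** Peaks on one chromosome are merged when their gap is
*strictly less than* 12,500 bp. The gap between two peaks is the start of
the later minus the largest end seen so far in start-sorted order, so
nested and overlapping peaks always merge; the result equals the
transitive closure of the pairwise gap relation (the test suite checks
this against an explicit graph-component oracle). At exactly 12,500 bp
two peaks stay separate — the boundary is exclusive, and both the tests
and the acceptance script sweep the boundary at 100-bp resolution to pin
it.

**Ranking.** Each stitched region's tag count is the coverage mass
overlapping its hull, prorated linearly within partial bins and scaled to
reads-per-million of the sample's own track. There is no input-control
subtraction (none is part of the upstream protocol this mirrors) and no
promoter/TSS exclusion (ROSE offers one; the procedure reproduced here
does not use it). Scaling the track by any constant leaves ranks
unchanged.

**Designation.** Regions are sorted by tag count; the top 5% —
`max(1, floor(0.05 * N))` regions — are designated super-enhancers.
`floor` with a minimum of one is the conservative reading of "top 5%" at
small N. Ties are broken deterministically: tag count descending, then
region length descending, then (chromosome, start) ascending. Total
order matters more than any particular choice here; reruns must be
byte-identical.

# Differential gains and cross-line intersection

A treated-condition SE with **zero** bp of overlap against every parental
SE is *gained*; a parental SE with zero overlap against all treated SEs is
*lost*; ≥ 1 bp of overlap makes the pair *shared*. Gain is deliberately a
presence/absence call, not a signal fold-change: the design this package
reproduces reports discrete gained/lost counts with no fold-change
threshold, so set semantics is the faithful reading. No reciprocal-overlap
fraction is imposed; 1 bp suffices.

Gains from the two lines are then intersected: gains of line A overlapping
gains of line B (≥ 1 bp, transitively) form one *merged common-gain
region* whose interval is the union hull of all contributors — hulls can
therefore be larger than any single SE. Components that contain only one
line's gains are dropped. Ids are assigned in (chromosome, start) order.
The grouping is checked against a bipartite connected-components oracle.

# Gene annotation

Genes are assigned to merged regions with a three-word vocabulary:

* **in gene** — region and gene body overlap by ≥ 1 bp (distance 0);
* **upstream** — the region lies entirely on the gene's 5' (TSS) side;
* **downstream** — otherwise.

Orientation is the *gene's* strand; flipping a gene's strand swaps
upstream and downstream exactly. Flank annotations are limited to a
50 kb window (edge-to-edge), a conventional enhancer-to-target assignment
span chosen because the source material states none; it is configurable,
"in gene" calls ignore it, and enlarging it never removes an annotation.
Because the original annotation used an unknown gene build and window,
exact reproduction of the published position labels is not asserted
anywhere — only self-consistency (each published prognostic gene, placed
at its printed coordinates, annotates to its published host region).

# The prognostic screen

All expression values are log2 scale.

* **Upregulation.** Per gene, Welch's two-sided t-test (tumor vs normal)
  with p < 0.05 *and* tumor mean above normal mean. No FDR at this step —
  the screen this mirrors applies a plain 0.05 rule, and the survival
  filter below multiplies the false-positive protection.
* **Survival.** Tumor patients are split at the median of each gene
  (strictly above → high; ties go low, the deterministic reading of
  "high expression group"). Follow-up is truncated at 1,825 days (5
  years) with events beyond the horizon censored. High vs low is compared
  by the standard 1-df log-rank test; Kaplan-Meier curves use the
  product-limit estimator. Genes passing both filters are the
  *prognostic set*.
* **Alterations.** A tumor sample is *altered* for a gene when its
  Z-score — (value − cohort mean)/cohort SD over all tumor samples — is
  ≥ 0. The reference is the expression cohort itself; diploid-referenced
  Z-scores (as used by cBioPortal) need copy-number calls this package
  does not model, and the divergence is deliberate and documented.
* **Mutual exclusivity.** Every unordered pair of prognostic genes is
  cross-tabulated (altered/unaltered); association is a two-sided Fisher
  exact test with a log2 odds ratio (Haldane correction of 0.5 per cell
  when any cell is zero). Benjamini-Hochberg adjustment is applied within
  the pair family. Odds ratio above 1 reads as co-occurrence, below as
  mutual exclusivity.
* **GSEA.** Genes are ranked by log2 fold change of altered-in-any vs
  non-altered patients (the ranking metric of the original web service is
  not recoverable; fold change of means is the plain choice). Enrichment
  is the classic weighted Kolmogorov-Smirnov walk with weight exponent 1;
  the null is gene-label permutation (same-size random sets), NES divides
  the observed ES by the mean |null ES| of matching sign, and FDR is
  estimated sign-stratified from the pooled null. Sets with fewer than
  two members in the ranking are skipped with a warning. The ES
  computation is cross-checked against an independent implementation
  (`fgsea::calcGseaStat`) in the tests.

Multiple testing is corrected within each family separately (exclusivity
pairs; GSEA sets), never across stages.

# The synthetic study

The generator emulates the study design end to end; its defaults are the
package's reference conditions.

**Genome and loci.** Two 5-Mb chromosomes. Twelve constitutive SE loci are
planted (present in both lines and both conditions), plus treated-only
gains: five loci at identical coordinates in both lines (the common gains
the pipeline must recover) and two private to each line. Each locus is a
cluster of 5–8 member peaks of 800–1,500 bp separated by gaps drawn from
[1,000, 11,000) bp — always below the stitch distance, so each locus
stitches into exactly one region. One *boundary-control* locus with
3 peaks spaced 13–15 kb apart is planted in every sample; its peaks are
enriched like an SE but must never merge, exercising the stitch boundary
inside every end-to-end run (it is planted in all samples precisely so
that it can never masquerade as a gain). 450 isolated background peaks of
500–2,000 bp per line are placed on a 15-kb grid in the space left free
by the loci, so background peaks neither merge with each other nor with
planted loci and the stitched-region count is predictable (~465 parental,
~472 treated; the top-5% rule then designates 23 — comfortably above the
22 planted strong regions in a treated sample). Background layouts differ
between the lines (line-specific seeds): a noise-driven spurious gain in
one line then has essentially no chance of overlapping a spurious gain in
the other, which is exactly the robustness the two-line intersection is
designed to provide.

**Fragments.** 75-bp single-end-like fragments, 200,000 per sample
(exactly — a multinomial split between the uniform background and the
enriched windows), with member-peak windows at 10× background density.
MAPQ values include a low-quality minority so the coverage filters do
real work.

**Cohort.** 300 tumors, 30 normals. Expression is
Normal(baseline, 0.5) per gene on log2 scale; four planted genes — drawn
from the genes within 50 kb of shared-gain loci, so the ChIP and screen
halves of the pipeline meet — get +1.0 log2 units in tumors. Tumor
survival is exponential with hazard
λ₀ · 2^(number of planted genes above their median), λ₀ = log(2)/1200
days, censored by an independent U(500, 3650)-day follow-up. The baseline
and censoring are the package's own calibration: with four multiplicative
planted effects the *marginal* per-gene hazard ratio is attenuated
(non-collapsibility), and these values were fixed once, by a standalone
power computation, so that the planted per-gene effect is detectable with
essentially unit power at the default cohort size — i.e. the generator
actually exhibits the effects it claims to plant. The planted effect
sizes themselves (HR 2.0 per gene, +1.0 log2, n = 300/30) are the study
conditions and were not revisited.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: read-level sequence and mappability
structure, input-control background shape, copy-number-driven expression,
correlated (co-regulated) gene modules, non-exponential hazards, and
informative censoring. The generator's background peaks are regularly
spaced and its fragment background is uniform; real H3K27ac background is
neither. Recovery results on synthetic data demonstrate the pipeline's
*logic* (set semantics, thresholds, normalization, statistics), not
calling performance on GEO-scale data.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; zero-length intervals are
  rejected at construction. The packaged 68-region table is ingested
  verbatim (its printed lengths equal end − start, so no ±1 adjustment).
* Chromosome names are canonicalized to the `chr` prefix on request, not
  silently.
* Quantifying against an all-zero coverage track, ranking an empty region
  list, a median split of constant values, a log-rank test without
  events, and a zero-variance gene in alteration calls are all errors,
  not silent zeros.
* The boundary-control and every threshold (12.5 kb; 5%; MAPQ 25;
  p < 0.05; Z ≥ 0; 1,825 days) are exercised at their exact boundary in
  the tests.
* Problem sizes in the tests were chosen to keep the default suite within
  a few minutes on one core: oracle equivalence runs 1,000 random
  instances of up to 100 intervals; coverage conservation uses ≤ 10-kb
  toy genomes; the end-to-end recovery check runs the full default study
  over ten seeds; the Fisher cross-check enumerates all 2×2 tables with
  n ≤ 20.

# Known limitations

* Gain/loss is binary presence/absence; a fold-change-based alternative
  would need replicate modelling (DiffBind-style) that is out of scope.
* The alteration Z-score is cohort-referenced, not diploid-referenced.
* GSEA FDR uses the pooled permutation null across sets of each sign; with
  very few sets the estimate is coarse (the nominal p is exact to
  permutation resolution regardless).
* Only two cell lines are intersected; the grouping generalizes but is
  untested beyond two.
* The fixture inherits two OCR-garbled LOC identifiers and one orphan
  position label from text extraction; they are stored as printed and
  flagged in the loader documentation rather than silently repaired.

# Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 17)
dir <- tempfile("segain-")
paths <- write_simulation(cfg, dir)
res <- run_pipeline(pipeline_config(paths, file.path(dir, "out")))

# recovered common gains vs planted truth
truth <- planted_truth(cfg)
res$merged[, c("chrom", "start", "end")]
truth[truth$is_shared_gain, c("chrom", "start", "end")]

# the screen's prognostic genes
res$screen$prognostic_genes
```

The same chain, stage by stage and with printed summaries, is in
`analysis/01_simulate.R` through `analysis/05_published_regions.R`.
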