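---
title: "Methods: promoter methylome profiling from MeDIP tiling arrays"
author: "promethylome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter methylome profiling from MeDIP tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethylome)
```

## The problem

Methylated-DNA immunoprecipitation hybridised against input DNA on a
promoter tiling array (MeDIP-chip) measures, probe by probe, how strongly
a genomic fragment is enriched by an antibody against 5-methylcytosine.
Comparing such promoter methylomes across embryonic stem (ES) cells, ES
cell-derived germ layers (ectoderm, endoderm, paraxial mesoderm) and
adult tissues (brain, liver, skeletal muscle, sperm) asks three
questions: which promoter regions are methylated at all; which of those
are methylated in common across somatic lineages versus specific to a
tissue; and how promoter methylation relates to CpG density, histone
state (H3K4me3 / H3K27me3), and transcription.

`promethylome` implements that full analysis as a tested pipeline:
probe-level enrichment scoring with an empirical false discovery rate
(FDR), CpG-density-gated candidate methylated region (CMR) calling with
tri-state calls, cross-sample commonality categorisation and TSS-distance
profiles, testis-specificity gene-set enrichment (GSEA), and
histone-state integration. Because raw MeDIP-chip studies of this design
are not reproducible at desk scale, the package ships a first-class
synthetic-data generator that plants a known methylome with the
statistical structure the analysis assumes, so every stage can be
validated against ground truth.

## The synthetic study

`sim_config()` fixes the study design: each of `n_genes` promoters is
tiled by 25 probes spanning 6 kb upstream to 2.5 kb downstream of the
TSS; every sample contributes two MeDIP and two input arrays; testis
appears as an expression-only column. One synthetic chromosome is built
from 10-kb gene blocks. Promoter sequences are real nucleotide strings:
background bases are drawn at 42% GC, CpG-island cores (−1.2 kb..+0.7 kb
of the TSS on CpG-high and intermediate promoters) at 52% GC, accidental
CG dinucleotides are removed, and CpGs are planted on a jittered grid
whose rate sets the promoter class — 34, 22 or 5 CpG per 500 bp for
high / intermediate / low. Density computations therefore run on actual
sequence rather than labels, and the three classes respectively land in
the HCP / ICP / LCP regions of the observed/expected-CpG rule.

Planted region classes carry the cross-sample structure:

* **Commonly methylated germline promoters** (default 4% of genes):
  methylated (0.82–0.95) in every somatic sample, unmethylated in ES and
  sperm, and expressed only in the testis column.
* **Imprinting centers** (0.8%): level 0.5 in *every* sample including
  sperm — the allelic state. Despite the halved level, the saturating
  enrichment response keeps their region scores above the
  high-confidence threshold, which is why 0.5 rather than 1.0 was chosen.
* **Germ-layer T-DMRs** (2%): methylated in exactly one germ layer; a
  configurable 10% are maintained in the matched adult tissue
  (ectoderm→brain, endoderm→liver, mesoderm→muscle), the rest are
  early-only.
* **Cluster genes** (1.5%, runs of five adjacent genes): intermediate
  mosaic levels (0.35–0.75) in all somatic samples.
* **CpG-poor constitutive flanks**: with probability 0.7 per side,
  non-planted genes carry methylation from a random start position out
  to the edge of the probed span. These flanks create the V-shaped
  methylation frequency profile around the TSS and sit below the
  CpG-density gate.
* Everything else is an unmethylated core (level ≤ 0.05).

Class levels are drawn once per region and shared across samples of the
same role, so with `frac_tdmr = 0` all somatic samples have identical
truth — differences between samples come only from planted classes, and
measurement noise enters solely through the arrays.

Array intensities follow a lognormal error model (Gaussian on log2):
expected MeDIP enrichment is
`enrichment_slope × methylation × c/(c + cpg_half)` with `c` the probe's
CpG count per 500 bp (`cpg_half = 5`), plus a per-probe affinity effect
(sd 0.15) shared across arrays and independent noise (sd 0.35). The
default slope of 4 was calibrated so that fully methylated CpG-rich
regions score far above the high-confidence threshold and imprinting
centers clear it at the region level *after* robust standardisation —
the genome-wide methylated background inflates the per-array MAD, which
attenuates standardised enrichment, exactly as it does on real arrays.

What the generator does **not** emulate: probe sequence-composition
bias (the reason the original tiling-array scorer fits a probe model),
cross-hybridisation, amplification bias, spatial artefacts, batch
effects, and copy-number variation. Passing tests on this generator
therefore validate the statistical logic of the pipeline, not its
robustness to platform-specific artefacts.

## Probe scoring and the effective count

Arrays are first robust-standardised (median-centred, unit MAD). For a
probe, the score pools the standardised MeDIP-minus-mean-input
differences of all probes whose centers lie within ±`window_bp/2`
(each MeDIP replicate contributing one value per probe) and computes

> score = trimmed mean × √(effective count),
> effective count = n_probes × r_m·r_i / (r_m + r_i),

where `r_m` and `r_i` are the numbers of MeDIP and input replicates and
`n_probes` counts distinct probes surviving the trim. The harmonic
replicate correction is the variance-exact choice: the variance of the
window mean of these differences is `(1/r_m + 1/r_i) / n_probes`, so the
score has unit variance under the null for *any* replicate design. That
matters for FDR calibration, because the null track is built by an
input-replicate label swap (input 1 plays MeDIP against input 2), a
1-vs-1 design; with the harmonic correction the swap track lands on
exactly the observed null scale instead of being √2 inflated.

Defaults are `window_bp = 800`, `trim_frac = 0.1`, `min_probes = 3`
(pooled values). With 25 probes across 8.5 kb the probe spacing is
~354 bp, so an 800-bp window holds three probes (six values) for MeDIP
scoring and three values for the swap null; a narrower window would
leave the null track with a single probe and no score. For the same
reason region assembly bridges inter-probe gaps up to
`max_gap_bp = 400` — one probe spacing in this layout — so that a run of
consecutive positive probes is never split by placement jitter.

The empirical FDR at threshold *s* is
`100 × min(1, null exceedance rate / observed exceedance rate)`,
regularised to be monotone non-increasing by a running minimum from low
to high thresholds. With the rate (rather than raw-count) form the
estimate is unchanged when both tracks cover the same probes and remains
meaningful when missingness differs.

## CMR calling and tri-state calls

Per sample, maximal runs of probes scoring above 2.5 become candidate
intervals; intervals from all samples are merged wherever they overlap
(`GenomicRanges::reduce`), giving one region set shared by all samples.
A region is kept when its CpG density — the mean of its member probes'
500-bp window densities — exceeds 5% *and* its score exceeds 3.0 in at
least one sample. The per-sample region score is the maximum member
probe score (regions are peak-like), and the tri-state call is:
methylated above 2.5, hypomethylated below 1.5, indeterminate in
between; the boundary values themselves are indeterminate because both
confident classes are defined by strict inequalities.

## Commonality categories

With samples partitioned into roles (ES lines; the three germ layers;
adult somatic tissues; sperm; somatic = germ layers ∪ adult), regions
are categorised by walking a precedence order and returning the first
category whose conditions hold definitively:

1. `all_positive` — methylated in every sample including sperm;
2. `sperm_any_others_positive` — methylated in every non-sperm sample,
   sperm unconstrained;
3. `somatic_common` — methylated in every somatic sample, ES and sperm
   unconstrained;
4. `early_diff_only` — methylated in all three germ layers and
   hypomethylated in every adult tissue;
5. otherwise `variable`.

Indeterminate states are handled tri-valued: a category is *violated*
only when some decisive sample is confidently on the wrong side, and
*blocked* when only indeterminate states stand in the way. A region
matching no category but blocked somewhere is reported as `other`
(unclassifiable) rather than `variable`. Returning the first
*definitively satisfied* category (rather than failing on any blocked
earlier category) keeps, e.g., a region with an indeterminate sperm
state but clean somatic methylation in `somatic_common`, which is the
scientifically intended reading. T-DMRs are regions with at least one
methylated and one hypomethylated sample; indeterminate samples count
for neither side.

Two windows around the TSS are deliberately distinct: zone tables
(core / tss_up / tss_down) use −1 kb..+0.5 kb, while gene-level
methylation extraction uses the core promoter −1.5 kb..+0.5 kb. Both are
configurable (`core_zone`, `core_window`). Regions are attached to the
nearest TSS by midpoint distance, strand-aware, with equidistant ties
resolved to the lexicographically lower gene id; assignment of a region
overlapping several promoters is a genuine modelling choice and nearest
midpoint is the package's.

## TSS profile

The methylation frequency at a TSS offset is the number of probes with
score above 2.5 divided by all probes at that offset bin (default
100 bp), smoothed by a centred moving average spanning 200 bp (rounded
to an odd number of bins; the window shrinks at the profile edges). On
the synthetic study this reproduces the canonical V shape with its
minimum inside ±1 kb of the TSS.

## Testis-specificity GSEA

Genes are ranked by testis expression divided by the maximum somatic
expression, floored at 1.0 on the mean-100 normalised scale so that
silent somatic genes do not divide by zero. Enrichment uses the weighted
Kolmogorov–Smirnov running sum — hits increment by |score|^p normalised
over the set, misses decrement by 1/(N−N_hits) — with `p = 1` as the
default weighting (exposed as a parameter because the weighting scheme
is a free choice here). Significance comes from 1000 gene-label
permutations with add-one smoothing, `p = (1 + #{null ES ≥ ES})/(1 + n)`
for positive ES (mirrored for negative), so `p` is never 0 and its
resolution is 1/(n+1); `NES = ES / mean(|null ES| of the same sign)`.
The expression generator normalises every array to mean 100 on the
linear scale.

## Histone states

Per histone sample each gene is in {H3K4me3, H3K27me3, bivalent, none},
determined in the analysis solely by ≥1 bp peak overlap with the closed
TSS ± 2 kb window. The generator draws states conditionally on the
gene's core methylation and solves the conditional state frequencies so
that the realised P(methylated | state) hits the configured targets
exactly (defaults 2% for K4, 15/25/35% for bivalent/K27/none) given the
sample's methylated fraction. In weakly methylated samples (ES) the
targets are infeasible and are scaled down by a common factor, which
preserves their ordering — H3K4me3 stays the least methylated state.
The fraction of genes that lose H3K4me3 and gain methylation between
the ES-like and differentiated samples is not a separate knob: it is
realised by the germline and cluster classes, which gain methylation at
differentiation.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open throughout (BED convention); GFF3 is
  converted at the file boundary; malformed lines fail with their line
  number; unsorted input is sorted.
* CpG counting is a non-overlapping left-to-right scan; for the
  self-inverse dinucleotide CG the distinction from overlapping counting
  is moot, but it is the documented behaviour. Windows truncated at
  chromosome ends use the realised window length.
* Promoter CpG classes use 500-bp windows sliding by 25 bp over
  −700..+200 bp of the TSS: HCP if any window has observed/expected
  ≥ 0.75 *and* GC ≥ 0.55 (both inclusive), LCP if no window reaches
  o/e 0.48, else ICP. CpG count, GC and the C·G product are
  strand-symmetric, so the plus-strand window serves both strands.
* Constant arrays cannot be standardised and fail loudly; missing
  scores (windows under `min_probes`) yield indeterminate calls, never
  silent zeros.
* All generators are deterministic functions of `seed`; pipeline stage
  seeds are derived from it, and a pipeline rerun with the same
  configuration is byte-identical.

## Problem sizes

The packaged tests exercise the pipeline end to end at 5000 promoters
(125 000 probes, 36 arrays) for the full-scale properties — region
recovery, FDR calibration, profile shape, GSEA power and calibration
(200 random-set repeats), histone exclusivity — and at 120–400 promoters
for unit-level properties and determinism checks. The acceptance script
reruns the 5000-promoter study from scratch for any seed.

## Limitations

The scorer is a declared, fully specified statistic in the spirit of
model-based tiling-array analysis, not a reimplementation of it: there
is no probe sequence model, so platform-dependent probe effects are
handled only by the robust standardisation and the paired input
contrast. Threshold constants (2.5 / 3.0 / 1.5, 5% CpG, ±2 kb,
−1.5 kb..+0.5 kb, mean 100, 1000 permutations) are field conventions for
this assay and are all exposed as configuration. Conclusions about real
arrays additionally depend on artefacts the generator deliberately
omits (see above).
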