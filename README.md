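# promethylome

Promoter DNA methylation profiling from MeDIP tiling arrays, across
embryonic stem (ES) cells, ES-derived germ layers and adult tissues.

## What it does

MeDIP-chip experiments hybridise methylated-DNA immunoprecipitate
against input DNA on a promoter tiling array (~25 probes per promoter,
−6 kb..+2.5 kb of the TSS, duplicate arrays per sample). `promethylome`
turns such probe intensities into a promoter methylome and compares it
across samples:

1. **Probe scoring** — arrays are robust-standardised (median/MAD on
   log2); each probe gets a windowed score
   *s = trimmed mean × √(effective count)* of the pooled standardised
   MeDIP−input differences, with the effective count
   `n_probes · r_m r_i/(r_m + r_i)` chosen so the score has unit
   variance under the null for any replicate design.
2. **Empirical FDR** — a null track from an input-replicate label swap
   gives `FDR%(s) = 100 · min(1, null rate ≥ s / observed rate ≥ s)`.
3. **CMR calling** — runs of probes with `s > 2.5` merged across
   samples become candidate methylated regions (CMRs); regions are kept
   when their CpG density (mean member-probe 500-bp density) exceeds 5%
   and `s > 3.0` in at least one sample. Per-sample tri-state calls:
   methylated (`> 2.5`), hypomethylated (`< 1.5`), else indeterminate.
4. **Cross-sample analysis** — TSS-distance methylation frequency
   profiles (#probes with s > 2.5 / #probes per offset bin), CpG-island
   and promoter-zone tables, commonality categories
   (all-positive / sperm-unconstrained / somatic-common /
   early-differentiation-only / variable), and T-DMR extraction.
5. **GSEA** — genes ranked by testis / max(somatic) expression
   (mean-100 normalised arrays); weighted Kolmogorov–Smirnov running
   sum with a 1000-fold gene-permutation null (NES, add-one p).
6. **Histone integration** — promoter states {H3K4me3, H3K27me3,
   bivalent, none} from peak overlap with TSS ± 2 kb, percentage
   methylated per state, state-transition tables between samples, and
   expression comparisons (Welch t on log2(x+1)).

Because the original array data are not required, the package includes
a first-class synthetic-data generator (`sim_config()`,
`simulate_methylome_study()`) that plants a known methylome — commonly
methylated germline promoters, imprinting centers at the allelic level
0.5, germ-layer T-DMRs, mosaic gene clusters, CpG-poor constitutively
methylated flanks, H3K4me3 anti-correlated with methylation, and
expression suppressed by core-promoter methylation — on real synthetic
sequence with controlled CpG density. Every analysis stage is tested
against this planted truth. See the methods vignette
(`vignettes/promethylome-methods.Rmd`) for the model details.

## Worked example

```r
library(promethylome)

cfg <- pipeline_config(sim = sim_config(n_genes = 1000, seed = 1))
res <- run_pipeline(cfg)          # add out_dir = "run1" to write tables

res$fdr
#>   threshold n_observed n_null     fdr_pct
#> 1       1.5      67017   6566 16.84573972
#> 2       2.5      51100    418  1.40646708
#> 3       3.0      39621     76  0.32980888
#> 4       4.0      14735      2  0.02333748

nrow(res$cmrs)                    # 82 candidate methylated regions
res$commonality$counts
#>                    category  n
#> 1              all_positive  6
#> 2 sperm_any_others_positive  0
#> 3            somatic_common 50
#> 4           early_diff_only  0
#> 5                  variable 20
#> 6                     other  6

res$gsea
#> GSEA: ES = 0.998, NES = 1.371, p = 0.000999 (56 genes, 1000 permutations)

res$meth_by_state$Ect
#>      state n_genes n_methylated pct_methylated
#> 1       K4     802           21       2.618454
#> 2      K27      66           16      24.242424
#> 3 bivalent      75           12      16.000000
#> 4     none      57           18      31.578947
```

Reading the output: the score-1.5 threshold is noisy (FDR ≈ 17%) while
3.0 is stringent (≈ 0.3%), matching the two-tier calling rule. Most
classified CMRs are methylated in common across somatic samples; the
commonly methylated core-promoter gene set is strongly enriched in
testis-specific expression (positive NES, p ≈ 0.001); and promoters
carrying H3K4me3 are by far the least DNA-methylated state — the
mutually exclusive relationship between the two marks. The smoothed TSS
profile attains its minimum at +450 bp, inside the hypomethylated core
promoter.

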