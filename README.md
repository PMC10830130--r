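# tdsdquant

Quantitative pipeline for studying **target-directed small RNA
degradation (TDSD)** during programmed DNA elimination in ciliates.

During conjugation in *Tetrahymena*-like ciliates, ~26–32 nt scan RNAs
(scnRNAs) are produced from the germline genome, which contains
internal eliminated sequences (IESs) interleaved with
macronuclear-destined sequences (MDSs). scnRNAs matching the somatic
genome (MDSs) are selectively degraded after pairing with nascent
somatic lncRNAs; the surviving IES-matching scnRNAs later direct
excision of the IESs from the developing somatic genome. Failure of
TDSD (e.g. in mutants of the lncRNA machinery) leaves MDS-matching
scnRNAs intact and partially blocks DNA elimination.

`tdsdquant` provides, as tested and reusable R functions, the analyses
this biology is measured with — plus a synthetic-data generator with
known ground truth so every stage is testable without any external
download:

* **Genome tiling with an explicit mappability definition** — position
  `p` is mappable iff the k-mer starting there (k = 26, the shortest
  counted read) occurs at exactly one locus across the combined
  somatic + IES reference, both strands collapsed. MDS tiles are 10 kb
  windows kept iff they contain > 3 kb mappable sequence; each type-A
  IES is one tile.
* **Unique-match scnRNA quantification** — a 26–32 nt read is counted
  for a tile iff its exact occurrences (both strands) are confined to
  that single tile, normalized as
  `RPKM = count / (mappable kb) / (assigned reads / 1e6)`,
  with two-sided Wilcoxon rank-sum comparisons of per-tile
  distributions between timepoints and genotypes.
* **TDSD kinetics** — least-squares fit of
  `log(median RPKM + 0.1)` against time; the negated slope (clipped at
  0) is the per-hour degradation rate, fitted per genotype and
  compartment and ranked (expected ordering WT > EMA2-KO > EMA1-KO).
* **IES retention index** — per cell,
  `index = f x [(A_F−C_F)/(I_F−C_F)] / [(A_D−C_D)/(I_D−C_D)]`
  from FISH (F) and DAPI (D) mean intensities of new MAC (A), MIC (I)
  and cytoplasm (C); `f = 0.35` (the conventional rounded factor) by default, or re-derived so a
  complete-elimination-block control group has mean index exactly 1.
  Groups are compared with Welch's t-test.
* **SUMO-proteomics screen** — exclude nickel-bead binders (control
  log2 LFQ > 25) and poly-His proteins (> 6 consecutive H), then rank
  the rest by `log2(WT) − log2(KO)` to nominate candidate SUMOylation
  targets.
* **`run_pipeline()`** — one seed, one configuration, a full
  deterministic run with a structured report (optionally as JSON).

## Worked example

```r
library(tdsdquant)
report <- run_pipeline(default_run_config(seed = 1))
report$comparisons
```

```
  genotype kind n_tiles   U        p median_a median_b
1       WT  MDS      16 256 1.52e-06      228     11.6
2       WT  IES      20 184 6.75e-01    23512  24569.7
3  EMA2_KO  MDS      16 222 4.25e-04      749    392.0
4  EMA2_KO  IES      20 177 5.43e-01    21129  21992.6
5  EMA1_KO  MDS      16 128 1.00e+00     1084   1074.0
6  EMA1_KO  IES      20 207 8.60e-01    19148  18929.2
```

Between 3 and 8 hours post-mixing, the wild type loses most of its
MDS-matching scnRNA signal (median per-tile RPKM 228 → 11.6,
p ≈ 1.5e-06), the *EMA2* knockout loses it only partially, and the
*EMA1* knockout not at all (p = 1.0) — while IES-matching scnRNAs stay
flat in every genotype (all p > 0.5). The fitted kinetics recover the
simulated degradation rates (truth 0.6, 0.15, 0 per hour):

```r
report$decay_fits[report$decay_fits$compartment == "MDS",
                  c("genotype", "rate_per_h")]
#>   genotype rate_per_h
#> 1       WT    0.59459
#> 2  EMA2_KO    0.12945
#> 3  EMA1_KO    0.00176
report$genotype_order_mds
#> [1] "WT"      "EMA2_KO" "EMA1_KO"
```

The retention-index stage calibrates the complete-block control group
(`TWI1_KO`) to mean 1 and separates the partial-block group from wild
type (simulated true levels 0, 0.4, 1):

```r
report$retention$summary
#>     group  n    mean  median      p10     p90
#> 1      WT 20 0.00139 0.00246 -0.00856 0.00977
#> 2 EMA2_KO 20 0.38146 0.38744  0.35216 0.40803
#> 3 TWI1_KO 20 1.00000 1.01074  0.90536 1.07812
```

and the proteomics screen ranks the planted condition-dependent target
first, well clear of the background:

```r
head(report$screen$top_candidates[, c("protein_id", "delta", "rank")], 3)
#>     protein_id delta rank
#> 1        P0001 6.321    1
#> 212      P0221 1.585    2
#> 248      P0258 1.500    3
```

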