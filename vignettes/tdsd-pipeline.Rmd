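---
title: "Quantifying target-directed scnRNA degradation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying target-directed scnRNA degradation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsdquant)
```

## The system and the quantities

During sexual reproduction in ciliates such as *Tetrahymena*, the
germline micronuclear (MIC) genome is downsized into the somatic
macronuclear (MAC) genome by excision of internal eliminated sequences
(IESs) and re-ligation of the flanking macronuclear-destined sequences
(MDSs). The process is guided by ~26–32 nt Piwi-bound scan RNAs
(scnRNAs) produced from the germline genome. scnRNAs that pair with
nascent long non-coding RNAs transcribed from the parental MAC — i.e.
scnRNAs matching MDS sequence — are selectively destroyed
(target-directed small RNA degradation, TDSD), so that by
mid-conjugation the surviving pool is enriched for IES-matching scnRNAs
that later direct DNA elimination.

`tdsdquant` implements the quantitative machinery needed to measure
this process and its genetic perturbations:

1. a **synthetic-data generator** producing MIC/MAC genome pairs,
   scnRNA pools with genotype-specific degradation, per-cell FISH
   intensity tables and label-free proteomics (LFQ) tables, all with
   known ground truth;
2. **tile construction**: k-mer mappability masks, fixed-size MDS tiles
   and per-IES tiles;
3. **unique-match quantification** of 26–32 nt reads with RPKM
   normalization and rank-sum comparisons of per-tile distributions;
4. **decay kinetics**: first-order rate fits per genotype and
   compartment;
5. the calibrated **IES retention index** from two-channel intensity
   measurements, with Welch tests between groups;
6. a **SUMO-proteomics screen**: contaminant filters plus WT-vs-KO LFQ
   ranking.

Everything is deterministic given a parameter set and a seed, and
`run_pipeline()` executes the whole chain from one configuration.

## Models

### scnRNA production and degradation

The generator collapses production into a timepoint-0 pool. At each
sampling time $t$ (hours post-mixing), `reads_per_timepoint` candidate
reads are drawn: a genomic segment is chosen with probability
proportional to its production weight, a start position uniformly
within the segment, a strand by fair coin (lncRNA transcription is
bidirectional), and a length uniformly from 26–32 nt. Each candidate
then survives with probability

$$\Pr(\text{survive}) = e^{-\lambda_c \, t},$$

where $\lambda_c$ is the per-hour degradation rate of the candidate's
source compartment $c$: $\lambda_{\text{MDS}}$ is genotype-specific and
$\lambda_{\text{IES}}$ is 0 by default. Expected read mass per
compartment therefore decays exactly exponentially, with binomial
sampling error — the simplest kinetic form consistent with the
qualitative time courses the assay produces (strong loss of
MDS-matching scnRNAs in the wild type, partial loss in the *EMA2*
knockout, none in the *EMA1* knockout).

Default rates are $\lambda_{\text{MDS}} = 0.6$/h (wild type, so that
~95% of the MDS-matching mass is gone across the 3→8 h window), 0.15/h
(*EMA2* KO, a milder defect) and 0/h (*EMA1* KO, complete TDSD loss).
These encode the observed ordering WT > EMA2-KO > EMA1-KO; no
quantitative rate is established for this process, so the values are the package's chosen
study conditions, not claims.

Production is *not* uniform along the germline chromosome:

* scnRNA production is biased towards IESs and their flanking MDS
  regions. The per-bp production weight ratio defaults to
  `production_weight_ies : production_weight_mds = 15 : 1`. Beyond the
  biology, this choice controls a normalization artifact discussed
  below.
* Each locus (each IES, and each MDS segment between IESs) carries a
  lognormal production multiplier (meanlog 0, sdlog 0.5), drawn once
  per genome. Locus-to-locus output variability is a ubiquitous feature
  of small RNA landscapes, and it is what gives per-tile RPKM
  distributions their realistic heavy dispersion. Without it the
  synthetic tiles are implausibly homogeneous and even tiny systematic
  shifts become statistically detectable.

### Tiles, mappability and RPKM

The somatic sequence is cut into consecutive 10 kb windows (the final
partial window is kept and filtered by the same rule); a window is kept
iff it contains **strictly more than** 3 kb of mappable sequence. Each
annotated type-A IES is one tile, with no size or mappability filter.

"Mappable" needs an explicit definition (tiling pipelines often
leave it implicit); here, position $p$ is mappable iff the $k$-mer starting at $p$
occurs at exactly one locus across the combined reference — the somatic
sequence plus every IES sequence — counting a word and its reverse
complement as the same word. $k$ defaults to 26, the shortest counted
read length: a read can be placed uniquely iff its footprint contains a
word unique at read scale. The combined reference matters: a repeat
shared between an IES and an MDS locus must be non-mappable for the
MDS/IES dichotomy to be meaningful, and the generator plants exactly
such a repeat family in both compartments.

A read is assigned to a tile iff its exact occurrences (both strands)
across all tile sequences are confined to that single tile; multiple
occurrences *within* one tile still count as unique, because the tile is
the unit of quantification. Matching is exact string matching — reads
are error-free by design, so no aligner is imported. Counts normalize
as

$$\mathrm{RPKM}(T) \;=\;
\frac{\text{count}(T)}{\text{mappable kb}(T) \cdot
\text{(assigned reads)}/10^6}.$$

The "per million" denominator defaults to reads assigned to any tile;
`denominator = "length_filtered"` switches to all reads passing the
length filter. Tiles with zero mappable length are excluded.

**A caveat worth stating plainly**: RPKM is a *compositional* measure.
When the MDS compartment decays, the denominator shrinks, so
IES-compartment RPKM inflates slightly between timepoints (about 4% at
the default weights) and fitted MDS rates are biased slightly downward.
The 15:1 production bias keeps the stable IES compartment dominant in
the denominator, bounding this bias at roughly 2% (WT) to 11%
(*EMA2* KO) of the true rate — a closed-form mass-balance computation,
not a tuning. Fitted rates are estimates of the RPKM time course, not
unbiased estimates of the molecular rate; the recovery guarantees in
the test suite account for this.

### Distribution comparisons

Per-tile RPKM distributions at two timepoints are compared with the
two-sided Wilcoxon/Mann–Whitney rank-sum test: midrank tie handling,
exact enumeration when both samples have ≤ 8 observations and no ties,
otherwise the normal approximation with tie and continuity corrections;
the two-sided p doubles the smaller tail, capped at 1. Box-plot
summaries use type-7 (linear interpolation) quartiles, with either
Tukey 1.5×IQR whiskers clipped to the data or 10th/90th-percentile
whiskers — both conventions appear in this assay family.

### Decay fitting

Per genotype and compartment, the fit is least squares of
$\log(\mathrm{median\ RPKM} + \varepsilon)$ on time; the slope's
negation, clipped at 0, is the rate. The median across tiles (not
per-tile fitting) is robust to the heavy tile dispersion the generator
produces; the pseudocount $\varepsilon$ (default 0.1 RPKM) keeps the
log defined when a compartment is fully degraded. Two timepoints give
the exact two-point slope (standard error undefined, reported `NA`);
three or more give OLS with a standard error.

### IES retention index

Per cell, with mean intensities of the new MAC ($A$), the MIC ($I$)
and cytoplasm ($C$) in the FISH and DAPI channels:

$$\mathrm{index} \;=\; f \cdot
\frac{(A_F - C_F)/(I_F - C_F)}{(A_D - C_D)/(I_D - C_D)}.$$

The DAPI ratio normalizes for DNA content, the cytoplasmic subtraction
for background, and the MIC reference for staining efficiency; the
index is exactly invariant under independent multiplicative gains per
channel (each gain cancels within its ratio). Additive offsets do
*not* cancel in general — they only cancel insofar as the cytoplasmic
measurement captures the same offset as the nuclear regions, which is
exactly what the background subtraction assumes.

The factor $f$ defaults to the conventional rounded constant 0.35.
`calibrate_factor()` re-derives it as the reciprocal of the *mean* raw
ratio-of-ratios of a complete-elimination-block control group, which
makes that group's mean index exactly 1 by construction (the arithmetic
mean is used, not mean reciprocals, to match that convention). Cells
whose MIC intensity does not exceed the cytoplasmic background in
either channel have no defined index and are dropped with a warning
rather than failing the batch — manual region selection occasionally
produces such degenerate measurements.

The intensity generator is built so that the noise-free ratio-of-ratios
equals the group's true retention level exactly: FISH region means are
background plus $\text{retention} \times \kappa \times$ (DAPI excess),
with $\kappa = 2$ reflecting IES enrichment of the probe target in the
MIC. Additive Gaussian noise (sd 2, truncated at 0) is applied to the
six region means *before* the channel gains, so gain settings change
raw intensities but not a single downstream index at a fixed seed.
Group means are compared with Welch's unequal-variance t-test
(Satterthwaite degrees of freedom), n = 20 cells per group by default.

### Proteomics screen

Candidate SUMOylation targets are screened from a His-tag pulldown
comparison of a WT cross and a KO cross, with a no-tag mating control:

* proteins with control-condition log2 LFQ **strictly above 25** are
  flagged as nickel-bead binders (the control-run-only reading of the
  exclusion; a protein undetected in the control is never flagged);
* proteins with **more than six consecutive histidines** (a run of ≥ 7)
  are flagged as intrinsic bead binders;
* the rest are ranked by $\Delta = \log_2 \mathrm{LFQ_{WT}} -
  \log_2 \mathrm{LFQ_{KO}}$ descending, ties broken by WT abundance.
  Missing intensities are imputed at a detection floor (minimum
  observed log2 value minus 1) and flagged. No significance test is
  attached: the design is single-replicate, so the screen ranks rather
  than tests.

The LFQ generator plants the ground truth: one (or more) true targets
with $\Delta \geq$ `effect_log2` (the first being the most abundant WT
protein), bead binders with control log2 LFQ in (25.5, 30), poly-His
decoys carrying a 7–10 residue H run, and background proteins whose
WT/KO differences are clipped strictly below the planted effect.
Missingness is modelled as *left-censoring* below a detection-limit
quantile — the standard intensity-dependent missingness of label-free
proteomics — which is also what makes floor imputation sensible: a
protein missing in one condition was dim, so imputing it dim preserves
the detected-vs-not ordering without letting imputation manufacture
large apparent differences.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `genome_length` | 200,000 | bp | scaled-down germline chromosome; ~16 MDS tiles after excision |
| `n_ies` | 20 | — | enough IES tiles for distribution comparisons |
| `ies_length_range` | 1000–3000 | bp | scaled-down IES size class |
| `read_length_range` | 26–32 | nt | the scnRNA size class that is counted |
| `production_weight_ies/mds` | 15 / 1 | per bp | IES-centred production; bounds the compositional bias (above) |
| `decay_rate_mds_per_h` | 0.6 / 0.15 / 0 | /h | WT / EMA2-KO / EMA1-KO study conditions |
| `decay_rate_ies_per_h` | 0 | /h | IES-matching scnRNAs are not degraded |
| `timepoints_h` | 3, 8 | h | the assayed early/mid conjugation window |
| `reads_per_timepoint` | 50,000 | reads | depth at which rate recovery is tested |
| `k` (mappability) | 26 | nt | shortest counted read |
| `tile_size`, `min_mappable` | 10,000 / 3,000 | bp | the tiling rule (strict ">") |
| `pseudocount` | 0.1 | RPKM | keeps log defined at full degradation |
| retention `factor` | 0.35 | — | conventional rounded constant; recalibration returns full precision |
| `log2_threshold`, `his_run` | 25 / 7 | — | strict contaminant cutoffs |

## Numerical choices

* Coordinates are 0-based half-open everywhere, matching BED natively
  and eliminating a whole class of off-by-one errors.
* k-mers (k ≤ 26) are encoded base-4 into doubles (< 2^53, hence
  exact); canonical words are the elementwise minimum of a code and its
  reverse-complement code, and occurrence counting is sort-based. For
  k > 26 the implementation falls back to string keys.
* Multi-pattern exact matching uses Biostrings `PDict`/`vwhichPDict`
  per read-length class, against tile sequences and their reverse
  complements.
* Degenerate inputs: a fully tied rank-sum input returns p = 1 (the
  normal approximation is 0/0 there); two identical zero-variance
  samples return Welch p = 1, two different ones are an error; an
  all-zero normalization denominator is an error, not an NaN.
* Ties in genotype ranking break lexicographically and are flagged.
* Seeds: every generator takes an explicit seed and restores the
  caller's RNG state; `run_pipeline()` derives per-stage child seeds
  from the global seed by a fixed affine map modulo 2^31 − 1.

## What the generator does and does not emulate

It emulates: the excision relationship between the two genomes; a
repeat family shared between compartments (hence non-mappable tiles
and non-unique reads); bidirectional, locus-heterogeneous, IES-biased
scnRNA production; first-order genotype-specific TDSD; the
nucleus/cytoplasm structure and channel gains of intensity tables; and
contaminant classes plus intensity-dependent missingness of LFQ tables.

It does **not** emulate: sequencing errors or adapters (counting is
exact-match by design), real *Tetrahymena* genome composition (AT
richness, scaffold structure, the real IES size distribution),
chromatin state, secondary scnRNA production in the new MAC,
image segmentation (region means are tabulated directly), or
peptide-level proteomics. Passing tests therefore demonstrate the
correctness and statistical behaviour of the *procedures* under
controlled conditions — not that real libraries are error-free or that
real tile counts would be reproduced.

## Problem sizes used by the test suite

Unit tests run on 30 kb genomes with 5 IESs and a few thousand reads.
The end-to-end checks use the default study conditions (200 kb, 20
IESs, 50,000 reads per timepoint): one seed for the significance
pattern, 20 seeds for decay-rate recovery (mean absolute error within
20% of the true rate for genotypes with nonzero rates; mean fitted
rate ≤ 0.02/h for the zero-rate genotype, whose relative error is
undefined; ordering recovered in every run), and 20 seeds for screen
recovery. Oracle-equivalence suites run 50 random instances (≤ 5
tiles, ≤ 500 reads) against a quadratic brute-force matcher and 20
random references (≤ 5 kb) against brute-force k-mer counting.

## Known limitations

* Exact matching over tile sequences means a read straddling a 10 kb
  window boundary is unassignable (~0.3% of MDS reads at default
  sizes); the real assay has the analogous edge effect at tile ends.
* The compositional RPKM bias described above is inherent to
  per-million normalization; rate fits inherit it.
* The rank-sum comparisons between timepoints treat tiles as
  independent samples (as the box-plot comparison does), although the
  same tiles appear at both timepoints.
* `calibrate_factor()` normalizes the control *mean* to 1; with few
  control cells the factor itself is noisy, and the conventional rounded
  0.35 remains the default for comparability.

## A minimal run

```{r, eval = FALSE}
cfg <- default_run_config(seed = 1)
report <- run_pipeline(cfg, out_json = "report.json")
report$comparisons            # rank-sum significance matrix
report$decay_fits             # per genotype x compartment rates
report$genotype_order_mds     # recovered TDSD ordering
report$retention$summary      # calibrated retention indices per group
report$screen$top_candidates  # ranked SUMOylation candidates
```
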