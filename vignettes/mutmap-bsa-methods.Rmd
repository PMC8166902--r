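---
title: "Methods: bulked-segregant MutMap mapping with mutmapr"
author: "mutmapr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant MutMap mapping with mutmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The mapping problem

An EMS-induced recessive mutant is crossed to its (near-isogenic)
wild-type parent and the F2 generation segregates 3:1. DNA from two
phenotype bulks — plants with the wild-type phenotype and plants with the
mutant phenotype — is pooled and sequenced. At a site unlinked to the
causal locus both bulks carry the mutant allele at frequency ~1/2; at
the causal site the mutant bulk is *fixed* for the mutant allele
(frequency 1, because the trait is recessive) while the wild-type bulk
sits near 1/3 (the phenotypically normal class is 1/3 homozygous
wild-type, 2/3 heterozygous, so the mutant-allele frequency among them
is 2/3 · 1/2 = 1/3).

`mutmapr` works on the read counts that summarise this design. For a
pool with `ref_reads` and `alt_reads` at a site,

* SNP index = `alt_reads / (ref_reads + alt_reads)`,
* ΔSNP index = mutant-pool index − wild-type-pool index.

The Δ index is ≈ 0 genome-wide and rises to ≈ 2/3 around the causal
locus; the mapping signal is a contiguous run of elevated window means
on one chromosome. The sign convention (mutant minus wild type) makes
the causal peak positive, and the published index pair at a causal site
(wild-type ≈ 0.27–0.42, mutant = 1) is what the arithmetic reproduces:

```{r}
delta_snp_index(wt_index = c(0.27, 0.42), mut_index = c(1, 1))
```

## Pipeline stages and the parameters that matter

`run_pipeline()` executes, in order: depth filter → SNP indices →
windowed scan → Monte-Carlo null band → region calling → location and
effect annotation → candidate filtering.

| parameter | default | units | rationale |
|---|---|---|---|
| `min_depth` | 7 | reads/pool | below ~7 reads a pool's index is dominated by binomial noise; sites failing in either pool are dropped before any index is formed |
| `window_size`, `step` | 1 Mb, 1 Mb | bp | tumbling 1 Mb windows; a sliding mode (`step < window_size`) is available when finer localisation is wanted |
| `band_reps` | 10 000 | replicates | empirical 95%/99% quantiles are stable to ±0.001–0.002 at this size |
| `level` | 0.95 | — | one-sided upper threshold; a recessive causal locus can only *raise* Δ |
| `index_threshold`, `index_tolerance` | 1.0, 0.1 | index units | see below |
| `bulk_size` | 25 | plants | enters the null model through the bulk allele-frequency distribution |

### The null confidence band

How a "95% confidence interval" for a windowed Δ profile should be
built is genuinely open (site-level vs window-level, analytic vs
simulated, one- vs two-sided). `mutmapr` uses a Monte-Carlo,
window-level, one-sided construction, which we document as a design
choice:

1. under the no-linkage null each bulk's allele frequency is the
   mutant-allele frequency among `bulk_size` F2 plants whose genotypes
   are drawn 1:2:1 — equivalently Binomial(2·`bulk_size`, 1/2)/2·`bulk_size`;
2. read depth is Poisson(`mean_depth`) conditioned on passing the same
   depth filter as the data, and alt reads are Binomial(depth, f);
3. one replicate statistic is the *mean* of `k` such site deltas, with
   `k` set to the observed median SNPs per window, so the thresholds are
   on the same scale as the window means they are compared against;
4. thresholds are upper empirical quantiles at 95% and 99%.

The construction is self-calibrating: a fresh null window exceeds the
95% threshold with probability ≈ 0.05 (this is asserted by the test
suite). A consequence worth knowing: with several truly null windows in
a genome, *some* spurious window exceeds the 95% line in a
correspondingly predictable fraction of experiments. Region calling
therefore never stands alone — the candidate filters (below) are what
reduce the call to single-SNP resolution.

### Candidate filtering

The filters mirror the MutMap logic: the site lies inside a called
region, the mutant-pool index passes the index rule, the alt allele
differs from the reference genome, and the final call is restricted to
coding sequence. `filter_candidates()` defaults to the strict rule
`mut_index = 1`. The pipeline, however, runs with
`index_threshold = 1.0, index_tolerance = 0.1`: with ~25× pools and a
1% per-read miscall rate the causal site shows a perfect index only
when *zero* reads err (probability ≈ 0.99²⁵ ≈ 0.78), so the strict rule
throws away a fifth of otherwise perfect experiments. A tolerance of
0.1 admits up to two miscalled reads at 25× while remaining ~4 standard
deviations above anything an unlinked site (index ≈ 0.5 ± 0.12 at 25×)
produces. With deeper data the tolerance can be tightened back toward
zero.

### Effect annotation

Locations are classified with precedence CDS > UTR > intron >
intergenic (UTRs are inferred as exon-minus-CDS when not annotated).
For coding SNPs the affected codon is found in spliced CDS coordinates;
for minus-strand genes the genomic alleles are complemented onto the
coding strand first. Effects follow the standard genetic code:
synonymous, missense, or nonsense when the alt codon is a stop. The
canonical causal event reproduced by the simulator is a genomic A→T
that reads T→A on the coding strand of a reverse-strand gene,
converting TAT (Tyr) to TAA (stop).

`scan_motif()` adds a small promoter utility: exact motif matches
(default the TGTCTC auxin-response element) reported relative to the
start codon with the convention A of ATG = +1, the base immediately
upstream = −1, and a hit located by its 5′-most base. Under this
convention a motif whose first base lies 245 nt upstream is reported at
−245. (Published spans such as "−245 to −239" cover seven positions for
a six-base motif; whatever convention produced them, the 5′-anchor
convention here is stated explicitly and used consistently.)

## The synthetic data generator

`simulate_dataset()` emulates the study design so that every stage can
be exercised without the original reads:

* **Cross and meiosis.** An F1 heterozygous at every marker produces
  gametes with Poisson crossover counts on a genetic map of 4 cM/Mb
  (Haldane model: uniform crossover positions, no interference).
  N = 307 F2 plants; recessive phenotype rule with a phenotyping-error
  knob that defaults to 0 (the study's classes were clean).
* **Mutation load.** 2000 background EMS SNPs, 98% of them G:C→A:T
  transitions (the canonical EMS signature), homozygous in the mutant
  parent and absent from the wild-type parent — i.e. no standing
  variation, as in a mutant × parental-line cross. One causal SNP
  (default chr1:16268 A>T) in the second exon of a three-exon
  reverse-strand gene whose promoter carries exactly one TGTCTC element
  at −245.
* **Pooled sequencing.** Bulks of 25; per site and pool depth ~
  Poisson(25) and alt reads ~ Binomial(depth, f(1−e) + (1−f)e) with
  e = 0.01.
* **Outputs.** Reference FASTA, GFF3 gene models, a two-sample AD/DP
  VCF and a truth table; byte-identical under a fixed seed.

Two deliberate simplifications are worth flagging. First, the toy
genome is 2 × 2 Mb, i.e. each chromosome spans only 8 cM, so *all*
sites on the causal chromosome are in strong linkage with the causal
SNP and the called region typically covers that whole chromosome; on a
real genome (hundreds of cM per chromosome) the same machinery
localises to ~1 Mb. Second, background SNPs are kept out of the causal
gene's CDS: at the simulated density (one SNP per 2 kb) a ~900 bp CDS
would otherwise carry a fully linked coding background SNP in a large
fraction of runs, and the generator's truth table is defined to contain
exactly one coding causal variant. Real EMS screens face exactly this
ambiguity — two linked coding mutations in one candidate interval must
be separated by transgenic complementation, not by mapping — so passing
the recovery test here demonstrates the pipeline's correctness, not
that real screens always end with a single candidate.

What the generator does *not* emulate: read-level errors correlated by
position (mapping artifacts), indels and structural variants,
multi-allelic sites, segregation distortion, and phenotyping noise.
Tests passing on these simulations therefore validate the statistical
machinery under the stated model, not robustness to artefacts upstream
of the allele-count table.

## Segregation testing

`chi_square_ratio()` tests observed phenotype counts against a
Mendelian ratio. For df = 1 the Yates continuity correction is applied
by default, with the deviation clamped at zero (`max(|O−E|−0.5, 0)`) so
a perfect fit scores exactly 0. The default is chosen because the
corrected statistic for 237:70 vs 3:1 is 0.679 while the uncorrected
one is 0.787 — reproducing the published value of 0.68 requires the
correction — and it is switchable (`continuity_correction = FALSE`).
The corrected test is conservative: its simulated type-I error at
α = 0.05 for n = 307 sits near 0.04 (asserted in the tests within
[0.025, 0.055]).

## Numerical and degenerate-input choices

* Index at depth 0 is undefined (`NA`), never 0/0; such sites are
  removed by the depth filter before indices are formed.
* Null-band depths are drawn conditional on passing the same depth
  filter as the data (rejection sampling; the truncated mass at 25× is
  ~3 × 10⁻⁵).
* Windows with zero SNPs are omitted rather than reported as 0; runs of
  threshold-exceeding windows are merged per chromosome.
* Empirical quantiles use R's default (type 7) interpolation.
* All coordinates are 1-based and inclusive (VCF/GFF3 convention);
  minus-strand arithmetic is handled by explicit coordinate maps and is
  fuzz-tested against the strand-involution property (the effect on a
  minus-strand gene equals the effect on its reverse-complemented
  plus-strand construct).
* Every stochastic stage takes an explicit seed; identical
  configuration + seed reproduces output files byte for byte.

## Problem sizes used by the shipped experiments

The repository's tests and acceptance script run: 100 end-to-end
simulated experiments (full defaults) for the recovery rate; 10⁴
replicates for null-band calibration and its coverage check; 10³ bulk
draws for the wild-type-bulk-index anchor (mean 1/3); 10⁴-plant F2s for
the 1:2:1 / 3:1 goodness-of-fit anchors; and 4 × 10⁴ gametes for the
Haldane map-function check. These sizes put Monte-Carlo error well
inside each assertion's tolerance band.

## Known limitations

* The null band assumes exchangeable, unlinked sites; windows partially
  overlapping a causal region dilute rather than sharpen the signal.
* With tumbling windows the region boundary is quantised to 1 Mb;
  use the sliding mode for finer edges.
* The effect predictor handles single-nucleotide substitutions in
  single-transcript gene models; splice-site disruption, multi-transcript
  genes and regulatory effects are out of scope.
* The candidate index rule presumes a recessive, fully penetrant trait
  and error-free bulk phenotyping; dominant traits would need the
  complementary logic on the wild-type bulk.
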