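---
title: "Detecting parallel adaptation from Pool-seq AFD scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel adaptation from Pool-seq AFD scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

`afdscan` analyses pooled-sequencing (Pool-seq) allele counts from
multiple populations that colonised two ecologically distinct derived
habitats — here labelled *basic* and *acidic* lakes — from a shared
ancestral population for which a present-day *marine* proxy is available.
Three questions drive the pipeline:

1. **Parallelism.** Do the same genomic regions differentiate basic from
   acidic populations across independent lake pairs?
2. **Polarity of standing variation.** At those regions, is the allele
   favoured in the ecologically more extreme (acidic) habitat rare in
   the ancestor, while the basic populations retain the ancestrally
   common allele?
3. **Sweep asymmetry.** Did alleles that rose from lower ancestral
   frequency produce stronger selective sweeps — a larger local loss of
   diversity — in the habitat that selected them?

Because pooled sequencing yields population allele frequencies rather
than genotypes, every statistic is built on per-pool read counts, and
individual-like inputs (for trees and ordination) are *synthesised* from
the pools.

# Statistics and procedures

## Integrated AFD scan and core SNPs

Differentiation between two pools at a biallelic SNP is the absolute
allele frequency difference, AFD = |p1 − p2|, computed only where both
pools have ≥ 50× depth. Pairwise AFDs are averaged within comparison
categories — basic–acidic (B–A), basic–basic, acidic–acidic — requiring
at least 18 contributing pairs for B–A and 8 within habitats, so that a
category mean always reflects many independent population contrasts.
SNPs with pooled freshwater MAF ≤ 0.2 are excluded for information
content. An optional robustness variant divides each pair's AFD values
by that pair's genome-wide mean before averaging
(`standardize_pairs()`).

SNPs whose integrated B–A AFD strictly exceeds 0.70 are chained into
regions by single linkage: two passing SNPs on one chromosome belong to
the same region when separated by *less than* 50 kb, so regions
separated by at least 50 kb are independent. The *core SNP* of a region
is its maximal-AFD member, ties resolved to the smallest position so the
output is deterministic. The threshold can also be given as an empirical
quantile (type-7 interpolation; the convention matters little at
genome-wide SNP counts but is fixed for reproducibility).

## Polarity and ancestral asymmetry

At each core SNP the allele with unweighted across-population mean
frequency above 0.5 in the basic pools is the *basic allele*; the other
is the *acidic allele*. Population means are weighted equally (not by
depth) so that a deeply sequenced pool cannot dominate the habitat mean.
If the basic-habitat mean is exactly 0.5 the acidic habitat breaks the
tie; a SNP tied in both habitats is unpolarizable and dropped with a
warning. When the acidic allele's own habitat mean is not above 0.5 the
polarity rests on the basic habitat alone and a warning is raised.

Asymmetry is tested two ways:

* `sign_binomial_test(k, n)` — the exact two-tailed probability, under a
  fair coin, of an asymmetry at least as large as observing `k` of `n`
  core SNPs with the acidic allele as the marine *minor* allele
  (frequency strictly below 0.5; exactly 0.5 does not count):
  `p = min(1, 2 P(X ≥ max(k, n − k)))`.
* `median_permutation_test()` — compares marine acidic-allele
  frequencies at core SNPs against *matched random controls* (SNPs whose
  integrated B–A AFD lies within 0.5% of the genome-wide median, sampled
  without replacement), using |median difference| as statistic and
  `p = (b + 1)/(m + 1)` over `m = 9999` random relabelings. The +1
  correction is used because the identity relabeling is always a valid
  draw from the null. Small two-group problems can be enumerated
  exhaustively (`exact = TRUE`), in which case `p` is the exact tail
  fraction over all label assignments.

The tolerance for control matching is interpreted as *relative*
(±0.5% of the median AFD); an absolute window is available via
`mode = "absolute"` since the convention is a genuine judgement call.

## Synthetic genotypes, similarity, trees and ordination

For tree building, each population's discrete allele pool at a SNP is
reconstructed as `round(freq × 2N)` reference alleles among `2N` (ties
round up), and two alleles per synthetic individual are drawn without
replacement — all individuals at one SNP share the pool, so at most `N`
individuals can be synthesised from a pool of `N` diploids. Heterozygous
draws are encoded with IUPAC two-base codes and concatenated in SNP
order; sequences are exported as FASTA for external ML tree software.
In-package, a neighbor-joining tree (via `ape::nj`) provides the
topology check; NJ is reported rather than a likelihood tree because
model-based phylogenetics is outside the package's scope and NJ answers
the only question asked of the tree — which populations cluster.

The binary similarity matrix follows the pooled protocol: identify each
SNP's major allele over the global freshwater pool, sample one allele
per population with probability equal to its pool frequency, code it
1/0, and take Euclidean distances between the population vectors
(√ of the mismatch count). Ordination is non-metric MDS
(`MASS::isoMDS`, Kruskal stress-1), returned with stress as a fraction;
one axis is extracted for the ancestry contrast and two for general
structure. isoMDS cannot accept zero dissimilarities between distinct
objects, so zero distances (which arise when few SNPs are used) are
nudged up to half the smallest positive distance, with a warning.

## Sweep statistics

Within-population diversity around a focal SNP is summarised as the
number of SNPs with per-population MAF strictly above 0.3 in the 40 kb
window centred on it (windows are inclusive and clipped at chromosome
ends; zero-depth SNPs are missing, not zeros). A high MAF cut is used
because sweeps shift the frequency spectrum towards extreme values, so
high-MAF SNP density responds sensitively and — unlike nucleotide
diversity — is robust to prior mild MAF filtering of the SNP panel.
Counts are summed over a habitat's pools and divided by the analogous
1 Mb-window sum; the small window is *not* subtracted from the
denominator. The habitat contrast `delta = density_basic −
density_acidic` is then correlated (Pearson) with the acidic allele's
marine frequency, with a percentile bootstrap CI over SNP resampling
(10,000 iterations).

`pooled_pi()` implements a depth-corrected pooled nucleotide diversity,
`Σ [d/(d−1)] 2p(1−p) / window length`, purely as a comparison utility
for the SNP-density metric.

The genome-wide habitat diversity test takes each population's *median*
1 Mb-window high-MAF count across the control-SNP windows, uses the
absolute difference between the basic and acidic medians-of-medians as
statistic, and permutes habitat labels over populations. With five
populations per habitat there are only 252 label assignments, so the
null is atomic: the smallest attainable two-sided p is 12/252 ≈ 0.048,
and the random-sampling variant is conservative at α = 0.05. Exhaustive
enumeration (`exact = TRUE`) is therefore preferred at this design size
and is what the calibration checks use.

## Concordance between ancestral sub-samples

`major_axis_fit()` regresses the acidic-allele frequencies of one marine
sub-sample on the other along the *major axis* — the first principal
axis of the 2×2 covariance matrix — because both frequencies carry
sampling error of comparable size; ordinary least squares would
attenuate the slope. The 95% CI is a percentile bootstrap over points.
Note that the estimator is consistent for slope 1 when the two
coordinates are equally noisy observations of a common latent value;
with noise in only one coordinate the major axis is biased away from 1
by construction, which is why the recovery checks simulate noise in
both.

# The synthetic cohort generator

`cohort_config()` defines the simulated study; `simulate_cohort()` runs
it in three stages, each a separately testable function.

**What it emulates.** Five basic and five acidic lake pools of 30
diploids at a mean 63× depth; a marine ancestor-proxy sequenced as two
sub-samples (20 + 10 diploids) whose combined depth averages 133×, with
sub-sample depth allocated in proportion to pool size. Neutral SNPs get
ancestral frequencies uniform on [0.05, 0.95] — the flat spectrum
expected of long-segregating neutral polymorphisms — and each of 20
selected loci carries an acidic-favoured allele whose ancestral
frequency is uniform on [0.05, 0.45].

**Drift and selection.** Each lake evolves independently (no gene flow):
a founder bottleneck of 50 diploids, then 100 Wright–Fisher generations
at Ne = 500. Selection is imposed as a deterministic endpoint — the
locally favoured allele (acidic allele in acidic lakes, its alternative
in basic lakes) is set to frequency 0.95 — rather than via a
per-generation coefficient, because downstream statistics depend only on
endpoint frequencies and endpoint control keeps recovery tests stable.
These values give a neutral background whose integrated B–A AFD has a
genome-wide median near 0.25, with the 0.70 core threshold far in the
upper tail.

**Sweep footprints.** A linked SNP at distance `d` from a selected locus
has post-sweep frequency `p' = (1 − h) p_drift + h x`, where
`h = exp(−d/λ)` is the fraction of lineages descending from the founding
swept haplotype and `λ(p0) = lambda0 · ln(1/p0)/ln 4` grows as the
favoured allele's starting frequency `p0` falls — rarer standing
variants sweep harder and wider. `λ` equals `lambda0` (default 15 kb) at
`p0 = 0.25`. The allele `x` carried by the swept haplotype is drawn once
per linked SNP *per habitat* and shared by all populations of that
habitat, because parallel selection of the same standing variant drags
the same haplotype to high frequency everywhere — this is what produces
regions containing several SNPs near-fixed for alternative alleles
between habitats, the signature the scan keys on. Within a short
ancestral LD scale (`ld_scale`, default 5 kb, association decaying as
`exp(−d/ld_scale)`) a linked SNP is additionally a *perfect marker* of
the selected variant: its own ancestral frequency mirrors `p0`. Without
this, a detected core SNP that happens to be a hitchhiker would carry a
marine frequency unrelated to the sweep strength, and the negative
sweep-vs-ancestral-frequency correlation the analysis tests for could
not be observed at marker resolution.

**Read sampling.** Depth is negative binomial (size 100, i.e. mildly
over-dispersed relative to Poisson; floored at one read), and reference
read counts are binomial in the true frequency. The mild over-dispersion
is deliberate: at 63× mean depth, per-pool coverage must clear the 50×
scan floor almost always, or the ≥ 18-of-25-pairs rule would silence
most of the genome — incompatible with a design in which the large
majority of ascertained SNPs remain informative in the B–A category.
The dispersion parameter is exposed for users who want heavier-tailed
depth.

**Scaled-down design.** The default genome is 21 chromosomes of 2.5 Mb
(~1 SNP/kb at 50,020 SNPs). Relative to a full-size study this halves
the number of selected loci but doubles marker density, so each locus's
40 kb/1 Mb window statistics carry comparable information; total runtime
of the full pipeline stays near ten seconds. Selected loci are placed
away from chromosome ends and at least 2.5 Mb apart so that sweep
windows never overlap.

**Determinism.** A master seed is mandatory. Every population and every
pipeline stage draws from its own substream (a deterministic hash of the
seed and the stream name), so adding a stage or population never
perturbs another's draws, and two runs with the same configuration are
byte-identical.

**What it does not emulate.** No recombination maps, gene flow,
coalescent linkage beyond the deterministic footprint model, inversions,
reference bias, or locus-level depth correlation between pools.
Passing tests on this cohort demonstrate that the statistics recover the
planted structure under idealised sampling; they do not validate the
pipeline against alignment artefacts, cryptic population structure or
real LD patterns.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive; BED exports are 0-based half-open.
* Zero-depth cells are `NA` frequencies and propagate as missing —
  never as zero.
* The 12 bp spacing filter removes *both* members of a too-close pair
  (the only order-independent reading); the 1 Mb thinning rule is greedy
  left-to-right.
* Sync-format sites are reduced to their two most frequent nucleotides;
  a site whose third allele exceeds 10% of depth is dropped with a
  warning.
* Tri-state boundaries are all strict where the wording says "superior
  to"/"exceeding" (MAF filters, AFD threshold, high-MAF counting), and
  inclusive where it says "at least" (spacing, coverage, pair counts).
* `detect_core_snps` with no passing SNP returns an empty table, not an
  error; `correlate_bootstrap` refuses zero-variance inputs;
  `major_axis_fit` flags a vertical major axis instead of returning an
  arbitrary slope.

# Problem sizes used by the test suite

The acceptance-style checks run the default cohort (50,020 SNPs, 20
selected loci, 11 pools) once end-to-end; oracle-equivalence checks use
1,000 random small instances per operation family; calibration studies
use 500 null replicates per test. These sizes keep the full suite within
a few minutes on a single CPU while leaving each check statistically
meaningful.

# Known limitations

* The sweep footprint is deterministic given `h`; real hitchhiking is
  stochastic in both footprint width and within-window heterogeneity.
* The F_ST estimator is a Hudson-style parity utility, not a
  reproduction of any particular published estimator.
* `habitat_diversity_test` at the 5+5 design is inherently discrete;
  interpret p-values near conventional thresholds with the 252-atom
  null in mind.
* Marine sub-sample concordance assumes equal sampling noise in both
  sub-samples; strongly unequal depths would call for an
  errors-in-variables fit with unequal variances, which is out of scope.
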