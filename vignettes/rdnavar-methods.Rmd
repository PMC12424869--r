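---
title: "Calling and analysing rRNA variants in multi-copy rDNA: methods and design"
author: "rdnavar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analysing rRNA variants in multi-copy rDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnavar)
```

## The problem

The human 45S ribosomal DNA unit is present in hundreds of tandem copies on
the five acrocentric chromosomes. Its 18S and 28S rRNA genes are not
homogeneous: individual repeat copies carry sequence variants, concentrated
in hyper-variable expansion segments (ES) that protrude from the ribosome
core. Because the repeats are nearly identical, a 150 b short read cannot be
placed on a chromosome; what short reads *can* measure is the **frequency**
of each variant within a person's rDNA pool — an intrinsically quantitative
genotype in `[0, 1]`, unlike the discrete 0/0.5/1 dosages of single-copy
loci.

`rdnavar` implements the full analysis stack for this setting:

1. an **atlas model** — per-region allele sequences (combinations of
   variants observed within one ES or non-ES segment) extended with 150 b
   of non-variant reference flank so that reads longer than the segment can
   still be mapped, and per-region lookup tables mapping each allele to the
   single-nucleotide variants it carries;
2. a **perfect-match mapper** over the extended alleles;
3. conversion of allele counts to per-participant **variant frequencies**;
4. a segment-level **rare-variant burden** statistic;
5. **twin-based heritability** of variant frequencies;
6. covariate-adjusted **trait and disease association**;
7. a seeded **synthetic-cohort simulator** that makes the whole stack
   testable without controlled-access biobank data.

## Mapping by exact matching

Downstream counting uses only *perfect* alignments, so scored alignment
adds nothing: mapping is exact substring search. The index stores every
31-mer of every extended allele; a read (or its reverse complement) is
anchored by one seed k-mer and verified base by base. Two modes exist:

* **full** — the entire read must match verbatim;
* **quality-masked** — read positions with base quality at or below 20 act
  as wildcards; all other positions must match and no gaps are allowed.
  This is the convention used on real data, where sequencing errors carry
  low quality scores; the burden path uses it throughout.

In masked mode the seed is taken from a window of 31 consecutive
high-quality bases. Any true hit must match exactly on such a window, so
seeding remains complete; reads without a clean window fall back to an
exhaustive scan. A pure-R sliding-window scanner (`scan_reads_naive()`)
shares no machinery with the indexed C++ path and is used as the oracle in
the test suite.

Reads are classified per the unique-mapper definition: **unique** iff
exactly one allele (summed over all regions) has a perfect hit,
**multi-mapper** with two or more, else unmapped. A read hitting one allele
at several offsets counts one allele. SAM ingestion (`ingest_sam()`)
accepts external aligner output (`bwa mem -a` style, secondary alignments
kept) but re-verifies every record against the atlas before trusting it;
gapped CIGARs are excluded, and soft-clipped bases are accepted only in
masked mode and only when low-quality.

## From allele counts to variant frequencies

Within a region, the frequency of variant $v$ for participant $p$ is

$$\hat f_{pv} = \frac{\sum_{a:\,v \in \mathrm{lookup}(a)} c_{pa}}
                     {\sum_{a} c_{pa}},$$

where $c_{pa}$ are the allele counts under one of three policies:
`fractional` (default; a read hitting $k$ alleles contributes $1/k$ to
each, conserving read totals), `unique_only` (the burden convention) and
`all_hits` (a naive all-alignments count). A region with zero mapped reads
yields `NA` ("region unobserved"), distinct from an observed frequency of
zero. Variant keys are `position:ref:alt` with 1-based positions and
VCF-style left-anchored indels; cohort tables qualify them with the subunit
(`28S:60:G:A`) because the same raw key can legitimately occur on both
subunits.

Sidecar statistics follow the QC narrative of real cohorts: per-variant
mean read depth with a low-depth flag (strict `< 5000` reads), a
population-variability ranking (variance across participants, ties broken
by key, with the observed frequency range), and an rDNA copy-number proxy
`c45S = (rDNA reads / total reads) x scale`.

## Rare-variant burden

Per segment, with unique-mapper count vectors $u_p$:

* **Cohort support.** $\bar A$ keeps alleles with at least 2 unique
  mappers cohort-wide ("at least" semantics by default; a strict
  "more than" form is available via `strict = TRUE` since both
  conventions are seen for filters of this kind). One representative of
  the excluded,
  mutually indistinguishable remainder — its most atlas-abundant allele —
  is retained, giving $\bar A^+$.
* **Recount.** Reads whose hits fall only on excluded alleles of a single
  region become unique to the representative; reads mixing a resolved
  allele with excluded alleles stay multi-mappers (the conservative
  reading).
* **Depth QC.** Default depth is per-base coverage
  $d = \sum_a u^+_{ap} \cdot \ell_{\mathrm{read}} / L_s$; segments with
  cohort median depth below 30 are excluded. The raw count-over-length
  ratio is also available as `mode = "literal"`, but a median of 30
  *reads per base pair of segment* is an implausible bar for 150 b reads
  on short segments, so per-base coverage is the default.
* **Copy-scaled zeroing.** $\pi = u^+/\sum u^+$, $c = \pi \cdot c^{45S}$;
  entries below one copy are zeroed as somatic low-frequency clones,
  $\pi^\ast = c^\ast / \sum c^\ast$.
* **Statistic.** MAF is the largest $\pi^\ast$ of the segment (major
  allele frequency in the within-individual sense, not a population minor
  allele frequency); burden $= 1 - \mathrm{MAF} \in [0, 1]$.

Invariants enforced by tests: $\sum \pi^\ast = 1$ where resolved; zeroing
is monotone in the threshold; when $\bar A = A$ the pipeline reduces
exactly to plain unique-mapper frequencies.

## Twins, heritability and the depth confound

Monozygotic pairs are kinship `> 0.4` (strict), deduplicated greedily by
descending kinship because relatedness tables may list a participant
several times. Parent-offspring pairs are kinship in `[0.17, 0.35]`
(bounds treated as inclusive) with birth years more than 18 years apart;
trios are a child with two
parents not PO with each other. Heritability of a variant is estimated
directly as the cross-twin Spearman correlation of its frequency
(threshold `> 0.8` flags it heritable); no Falconer-style estimator is
attempted since only MZ pairs are used. Pair orientation is randomized
once per run under a recorded seed so input ordering cannot bias the
estimate. The depth confound is quantified as the Pearson correlation
between per-variant mean depth and twin correlation, before and after
removing low-depth variants; linkage among heritable variants is the
pairwise Pearson matrix with a hierarchical-clustering leaf order for
plotting.

## Association model

For each (predictor, trait) pair, complete cases only, the design is:
intercept, predictor, age, sex, age x sex, age², rDNA copy number, 20
genetic principal components, and one-hot batch indicators with the
lexicographically first level dropped. Quantitative traits use OLS on the
raw scale; disease indicators use maximum-likelihood logistic regression
with the predictor and continuous covariates z-scored (the normalization
is stated for the logistic path only, and the linear fit is kept on the
raw scale to match). Non-convergence — IRLS failure, rank deficiency, or
separation detected via boundary fitted probabilities — yields a flagged
row with no estimate, and the bookkeeping identity
`attempted = reported + non-converged` is enforced.

Disease codes are filtered to at least 30,000 cases (6% prevalence; the
prevalence form scales to synthetic cohorts). The Bonferroni threshold is
`alpha / (n_variants x n_traits)` with the **raw** trait count by default —
the most conservative choice, since definitions of an "effective number
of independent traits" vary between studies; a Li–Ji-style eigenvalue
estimate from the trait correlation matrix is available but never used
silently. QQ diagnostics report `-log10` expected/observed
quantiles and the genomic-control lambda (median chi-square ratio).

## The simulator: what it emulates, and what it does not

`simulate_atlas()` / `simulate_cohort()` / `simulate_reads()` generate:
subunit references tiled into ES/non-ES regions; per-region allele sets
(reference allele plus combinations of SNVs and left-anchored indels) with
a decreasing abundance spectrum; per-participant copy compositions of mean
400 copies (the "hundreds of copies" regime) drawn from a Dirichlet around
the atlas abundances, shared exactly within twin pairs; per-copy somatic
Bernoulli conversion of major-allele copies into low-abundance alleles
(`somatic_rate`, optionally coupled to copy-number expansion); 150 b reads
with uniform starts, a two-state Q37/Q10 quality mixture, substitution
errors always carrying low quality, and a logistic down-weighting of
high-GC windows (`gc_bias_strength`); and phenotypes linear (traits) or
logistic (diseases) in true frequencies or burden. Everything derives from
one seed; identical configs give byte-identical FASTA/FASTQ/TSV.

Two study designs are used deliberately:

* **Tiled design** (default): regions tile a subunit and share flanks, so
  flank reads multi-map across neighbouring regions — the realistic
  regime, used for mapper, classification and structural tests.
* **Isolated-region design**: each subunit is a single 150 b region, so
  every read spans its whole region and identifies its allele. Used for
  quantitative recovery studies, because with partially overlapping reads
  *no* counting policy is unbiased: reads that do not overlap a
  discriminating position are split uniformly among compatible alleles,
  shrinking frequency estimates toward uniform. The flank construction of
  the real atlas exists precisely because variant regions are shorter than
  reads, so this design isolates counting and conversion correctness from
  mapping ambiguity, which the mapper oracle covers separately.

Features of real data the simulator does **not** model: realistic Illumina
error profiles (two-state quality only), chromosome-of-origin and
Robertsonian structure (unresolvable from short reads anyway), GC-content
correlation between error rate and coverage, and novel variants absent
from the atlas (the pipeline only calls atlas variants, and imperfect
reads are discarded by design). Passing tests therefore demonstrate
algorithmic correctness under the stated generative model, not robustness
to every artefact of production sequencing.

## Numerical and design choices

* Coordinates are 1-based inclusive per subunit in memory and in TSV; BED
  on disk is 0-based half-open and converted on read/write.
* Indels are left-anchored with one shared reference base, and
  alignment-derived variant lists are left-shift normalized, so keys are
  deterministic in repeat context.
* Variant derivation for atlas rows without an explicit variant list uses
  global Needleman–Wunsch alignment (match 2, mismatch −3, gap open 5,
  extend 2) followed by the left-shift normalization; declared lists are
  validated by reconstructing the allele core from the reference.
* The k-mer seed length (31) affects speed only; correctness is
  verification-based. Masked-mode completeness follows from seeding on an
  all-high-quality window.
* `zero_threshold` is expressed in copy units (default 1); depth and
  support thresholds (5000; 30; 2) and kinship bounds are configuration
  values with the standard values as defaults.
* Degenerate inputs are non-fatal where the data may legitimately produce
  them: empty reads are logged and skipped, zero-support regions flagged,
  constant columns yield missing correlations, separation yields flagged
  non-converged rows.
* Statistical test thresholds that sit exactly on a null quantile (the
  0.15 twin-correlation bound at 177 pairs is 1.99 null standard
  deviations) are asserted with a one-sided binomial sampling allowance
  for the finite number of simulated draws, rather than on the raw
  fraction.

## Problem sizes used in the shipped studies

The package's verification studies run at desk scale, chosen to keep each
stage's sampling error well inside its tolerance: mapper oracle on 1,000
random 150-mers against 54 alleles; frequency recovery for one participant
at region depth 5,000 (binomial 3-sigma ≈ 0.019 at frequency 0.3, inside
the 0.02 band); burden invariants on 6 participants x 3 regions; twin
separation on 100 MZ pairs at depth 5,000 and the somatic null on 177
pairs x 16 replicates; association calibration with 1,000 null replicates
at n = 500 and spike recovery on 10 cohorts of n = 2,000.

## Known limitations

* Fractional frequencies are biased toward uniform when reads only partly
  overlap a region (see above); on real tiled atlases the output follows
  the convention of dividing by all reads mapped to the region rather
  than attempting an unbiased estimator.
* The burden path attributes collapsed reads to a single representative
  allele; when the excluded set is genuinely heterogeneous this
  concentrates its mass.
* `c45S` is a read-fraction proxy; its scale constant must be calibrated
  externally and GC bias is diagnosed (via depth statistics) but not
  corrected.
* Trio identification is provided, but no trio-level transmission
  statistic is computed downstream.
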