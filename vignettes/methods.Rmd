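---
title: "Methods: ROH detection, genomic inbreeding and diversity summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, genomic inbreeding and diversity summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rohdiversity)
```

This vignette documents the statistical model behind each stage of the
pipeline, the meaning and units of every tunable parameter, and the
numerical conventions the implementation commits to. It is the reference
for *why* the code does what it does; the function reference documents the
*how*.

## 1. Scope and data model

The package analyses a multi-sample genotype matrix: `n` diploid samples
by `m` biallelic SNVs, with calls coded as alternate-allele dosage 0/1/2
and `NA` for missing. The `geno_matrix()` container couples the call
matrix with a site table (chromosome, position, alleles, filter status)
and enforces the invariants the algorithms rely on: positions strictly
increasing within each chromosome, no duplicated sites, dosages in
{0, 1, 2, NA}.

Input is a VCF read with `read_vcf()` (built on `vcfR`); genotype fields
are mapped to dosage with half-calls (`./1`) treated as missing and phase
ignored. `filter_policy()`/`apply_filters()` implement the standard
working-set reduction: PASS records, biallelic SNVs only, per-site call
rate above a threshold (default 0.90, strict inequality), optional
chromosome allow-list. Filtering is idempotent.

## 2. ROH detection

### 2.1 Sliding-window scan

Detection follows the PLINK `--homozyg` window semantics. For one sample
on one chromosome, every window of `window_snp` consecutive SNVs (default
50) is classed *homozygous* iff it contains at most `window_het`
heterozygous calls (default 3) and at most `window_missing` missing calls
(default 5). Each SNV's *hit fraction* is the proportion of windows
containing it that are homozygous; the SNV is ROH-eligible iff that
fraction reaches `hit_threshold` (default 0.05) and the SNV's own call is
not heterozygous. Chromosomes shorter than one window are scanned with a
single truncated window.

Maximal runs of eligible SNVs become segments after four tests:

* runs are split where the distance between consecutive SNVs exceeds
  `max_gap_kb` (default 1000 kb), and each piece is re-tested;
* runs are trimmed so no segment starts or ends on a missing call;
* a segment must contain at least `min_snv` non-missing SNVs and span at
  least `min_kb` (default 300 kb);
* mean spacing must not exceed `max_kb_per_snv` (default 50 kb/SNV).

Coordinates are 1-based inclusive; segment length is
`end − start + 1`.

### 2.2 Calibration of the minimum SNV count

Under random mating a stretch of `l` consecutive SNVs is spuriously
homozygous with probability about `(1 − het)^l`, `het` being the mean
observed heterozygosity. Requiring

```
l ≥ ln(alpha / (n_samples · n_snvs)) / ln(1 − het)
```

bounds the expected number of chance ROH in the whole dataset below
`alpha`. `min_snv_threshold()` returns the ceiling of the ratio;
`detect_roh()` applies it automatically (with a message) when
`roh_params(min_snv = NULL)`.

```{r}
min_snv_threshold(alpha = 0.05, n_samples = 33, n_snvs = 6344366,
                  mean_het = 0.268)
```

At WGS density this calibrated count corresponds to a far shorter span
than the 300 kb length floor, so `min_kb` is the binding constraint; on
sparse genotyping arrays the calibrated count can dominate instead and the
shortest callable ROH grows accordingly. This interplay matters when
simulating (Section 7).

## 3. F_ROH and length classes

The genomic inbreeding coefficient of a sample is

```
F_ROH = (sum of its ROH lengths) / denominator
```

where the denominator is the surveyed autosomal extent:
`compute_denominator()` sums the first-to-last-SNV span per chromosome, or
accepts an explicit override when the surveyed length is known externally.
`froh()` refuses overlapping segments within a sample rather than silently
double-counting.

Segments are decomposed into six length classes — `<1`, `1–2`, `2–4`,
`4–8`, `8–10`, `>10` Mb — with half-open `[lower, upper)` binning, so a
segment of exactly 1 Mb falls in `1–2 Mb`. Because every segment falls in
exactly one class, the per-class F_ROH values sum exactly to the total;
tests enforce this partition property. `group_anova()` compares F_ROH
across cohorts with ordinary one-way ANOVA (`stats::aov`), returning a
tidy object with `tidy()`/`glance()` methods.

## 4. ROH islands

`snv_incidence()` computes, at every SNV, the fraction of samples whose
ROH cover it. `call_islands()` returns maximal runs of consecutive SNVs
whose incidence reaches the threshold (default 0.90). Two conventions are
deliberate:

* The sample-count cut-off is `ceiling(threshold · n − 1e-9)`, so
  "≥ 90% of 33 samples" means exactly 30 samples — the small epsilon
  guards against `0.9 * 33` floating below 29.7.
* Islands live in SNV-index space and have no minimum size; a single
  qualifying SNV is an island. Consumers can filter by `n_snvs`
  afterwards.

`annotate_islands()` intersects islands with gene features from a GFF3
(via `rtracklayer`) using *any-overlap* semantics: a gene touching an
island by one base pair is reported. `haplotype_audit()` checks whether
all samples are literally identical (homozygous for the same allele at
every non-missing SNV) across a region, and otherwise reports shared
heterozygous stretches of at least `min_run` consecutive SNVs — evidence
that the region harbours more than one haplotype.

## 5. Relatedness: pruning, Hamming distance, MDS

`ld_prune()` slides windows of `window_size` markers (default 1000)
advanced by `step` markers (default 100) along each chromosome. Within a
window, markers are visited in position order and a marker is removed when
its squared Pearson correlation of dosages with any earlier
still-retained marker exceeds `r2_max` (default 0.8). Removing the
*later* marker of an offending pair makes the retained set deterministic.
Correlations use pairwise-complete observations, computed exactly by
`r2_pairwise()` from cross-products of the zero-filled matrix and its
missingness indicator; constant columns get r² = 0.

`hamming_distance()` is the raw allele-sharing distance
`Σ |g_i − g_j|` over sites where both samples are called (opposite
homozygotes contribute 2); the per-pair number of shared called sites is
returned alongside so sparsity is visible, and a pair with no shared
called site is an error, not a 0. `classical_mds()` wraps
`stats::cmdscale` (eigendecomposition of the double-centred squared
distance matrix) and fixes the sign of each component so that its first
nonzero sample loading is positive, making coordinates reproducible
across platforms.

## 6. Trait variants, risk haplotypes, mtDNA

`genotype_counts()` tallies genotype classes for a shipped (or
user-supplied) table of trait-variant definitions; a variant absent from
the matrix is reported as `present = FALSE` with `NA` counts, never as
zeros. `allele_frequency()` is `(n_het + 2·n_homalt) / (2·n_called)`,
rounded to 3 decimals for reporting.

A multi-SNV risk haplotype's per-sample dose (0/1/2) is the consensus of
its defining SNVs' dosages — by default the median rounded half-up, an
explicit configuration point — with the discordance fraction always
reported for audit; a sample genotyped at fewer than half the defining
SNVs gets `NA`. The A/B/C `risk_index()` maps the total dose over loci
through monotone cut points (default totals ≤2 → A, ≤5 → B, else C).
**The default cuts are a non-authoritative placeholder**: the real
laboratory classification rule is proprietary, and users should supply
their own cuts when known. `compare_group_frequencies()` applies a
two-sided Fisher exact test to the 2×2 allele-count table.

`mtdna_haplotype()` assigns a maternal haplotype when *all* of its
defining variants are present in the sample's variant profile; ties
report all matched labels, extra variants are listed as unexplained, and
a non-match reports the best partial. The shipped definition table is a
synthetic stand-in — authoritative per-haplotype definitions should be
supplied for real assignments.

## 7. The synthetic cohort simulator

`simulate_cohort()` generates genotypes with known, planted autozygosity
so every stage can be validated against truth.

* **Sites** are uniform at `snv_density` per Mb (default 500).
* **Ancestral frequencies** are Beta(a, a) with `a` solved so the
  Hardy-Weinberg expectation `E[2p(1−p)]` equals `het_outside` (default
  0.268); frequencies are clamped to [0.005, 0.995].
* **Population structure**: samples are assigned round-robin to `n_pops`
  subpopulations whose frequencies are logit-normal perturbations of the
  ancestral ones with standard deviation `divergence`. The default 0.3
  produces the limited clustering typical of a single breed; separation
  experiments use 1.0.
* **Planted segments**: per sample, lengths are drawn from a
  six-component truncated-exponential mixture spanning the six length
  classes (first component starts at 300 kb so every planted segment is
  in principle reportable) and placed uniformly without overlap until the
  sample's `target_froh` is met; the last segment is trimmed to land on
  the target, and a sub-300 kb remainder is accepted as shortfall, so the
  realized fraction is within 1% of the target.
* **Genotypes**: homozygous at the site frequency inside segments,
  flipped to heterozygous with probability `error_rate` (default 1e-3);
  Hardy-Weinberg draws outside; a missingness mask (default 0.05) is
  applied last. Everything is deterministic given `seed` (mandatory).

An optional `shared_region` plants one fixed segment in a chosen fraction
of samples to emulate an ROH island. `truth_compare()` scores called
segments against the truth as base-pair recall and precision, per sample,
per planted length class, and overall.

Two limitations are intentional. The simulator has **no linkage
disequilibrium** outside planted segments (sites are independent), so it
cannot exercise LD pruning realistically — pruning tests use a separate
block-structured generator. And the default `snv_density` of 500/Mb is
chosen so that, as in WGS data, the 300 kb length floor (not the
calibrated SNV count, Section 2.2) is the binding detection constraint;
at much lower densities the calibrated count dominates and short planted
segments become undetectable by design, which biases F_ROH recovery low.

## 8. Numerical conventions

* Coordinates are 1-based inclusive throughout the API; BED export
  converts to 0-based half-open.
* Missing calls never terminate an ROH run (they are spanned) but are
  excluded from `n_snvs`, and segments are trimmed to called endpoints.
* Length-class binning is `[lower, upper)`.
* Window hit fractions are compared to the threshold with a 1e-12
  tolerance to absorb floating-point division noise.
* MDS component signs follow the first-nonzero-positive rule.
* LD pruning always removes the later marker of a correlated pair.
* All cohort-level outputs are sorted (sample, chromosome, start), so
  repeated runs on the same input are byte-identical.
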