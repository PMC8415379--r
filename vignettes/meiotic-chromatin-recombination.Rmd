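---
title: "Meiotic chromatin organization and recombination activity: methods"
author: "meiorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meiotic chromatin organization and recombination activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

During meiotic prophase I, chromosomes adopt a brush-loop architecture:
chromatin loops emanate from a proteinaceous axis that carries the
recombination machinery. Recombination initiates at hotspots marked by
PRDM9 binding, a subset of which receive programmed double-strand breaks
(DSBs, measured genome-wide by DMC1-SSDS ChIP-seq), and a yet smaller
subset of DSBs resolve as crossovers. `meiorec` provides a tested,
reusable pipeline that asks how the 3D folding of meiotic chromosomes —
read out from Hi-C — relates to which hotspots are favored at each of
these two transitions (PRDM9 → DSB, DSB → crossover).

The package computes, on a uniform genome tiling (5-kb bins by default):

* **cis/total ratio** — the fraction of a bin's Hi-C contacts that are
  intra-chromosomal. Low values indicate high spatial accessibility.
* **A/B compartment score** — the leading eigenvector of the
  observed/expected correlation structure, computed on 10-Mb diagonal
  chunks ("fine-grain" eigenvectors), because meiotic maps lose
  long-range signal too fast for whole-chromosome eigendecomposition.
* **Insulation score** — log2 ratio of contacts crossing a locus in a
  diamond window to the chromosome-wide mean; minima mark domain
  boundaries.
* **FIRE score** — a z-scored near-cis (15–200 kb) interaction
  frequency, normalized for the number of valid partner bins. This is a
  transparent reimplementation of the *meaning* of a FIRE score (locally
  enriched interaction frequency), not of any particular caller's
  internal regression; it is documented as an approximation.
* **P(s) curves and loop lengths** — mean contact probability versus
  genomic separation on a log grid, optionally restricted to bin pairs
  that share a compartment label, with the average loop length estimated
  as the distance at the maximum of d log P / d log s.
* **Crossover-score map** — each crossover resolution interval
  distributes unit mass 1/k over the k bins it intersects, so sharply
  mapped crossovers gain prominence; the map is normalized by its median
  over nonzero bins.

Site-level analyses then partition PRDM9 sites by DSB activity and DSB
sites by crossover likelihood, compare quartiles by log-fold enrichment
with Bonferroni-adjusted rank-sum tests, average tracks and
observed/expected contact windows around sites (with bootstrap
confidence intervals), and fit forward-selection linear models of DSB
and crossover activity on principal components of the chromatin
features.

# The synthetic genome

All of this is exercised end-to-end on a generator
(`sim_config()` / `simulate_all()`) whose defaults define the reference
study conditions used by the test suite:

| parameter | default | what it emulates |
|---|---|---|
| `chrom_lengths` | 3 × 60 Mb | a desk-scale genome |
| `bin_size` | 5 kb | the analysis resolution |
| `compartment_block_mean` | 2 Mb | alternating A/B blocks (exponential lengths) |
| `ps_exponent` | −1.0 | power-law contact decay |
| `loop_size_A`, `loop_size_B` | 0.7 Mb, 2.1 Mb | threefold-shorter A-compartment loops |
| `shoulder_amp`, `shoulder_sigma` | 0.6, 0.35 | loop shoulder strength/width on P(s) |
| `compartment_strength` | ES 1.0, zygonema 0.6, pachynema 0.8 | checkerboard contrast per stage; meiotic maps attenuated |
| `cis_fraction_base`, `cis_offset` | 0.8, 0.05 | cis/total anti-correlated with compartment (A lower) |
| `read_depth` | 5e6 / chromosome | shallow desk-scale sequencing |
| `n_prdm9_peaks`, `prdm9_frac_A` | 3000, 0.57 | hotspot counts, A-skewed placement |
| `dsb_bias_A`, `dmc1_noise_sd` | 2.0, 0.5 | DSB favoring of active chromatin |
| `n_crossovers` | 2000 | sperm-seq-style crossover intervals |
| `gene_body_penalty` | 0.2 | crossover depletion at gene-body DSBs |

Values not fixed by the modeled study conditions (stage-wise compartment
strengths, the shoulder amplitude, peak/crossover counts, ChIP noise
levels) were chosen once as field-realistic magnitudes: a same- versus
cross-compartment contact ratio of 2.0 for interphase and 1.6–1.8 for
meiotic maps matches the attenuation reported for meiotic Hi-C;
3000 hotspots on a 180-Mb genome give the site-level models a few
thousand quasi-independent observations, comparable in spirit (not in
count) to genome-wide hotspot sets; and 2000 crossovers sampled without
replacement from those hotspots leave the crossover map sparse, as real
single-sperm maps are.

Two deliberate design points deserve emphasis:

* **The loop shoulder is calibrated so that `loop_size` is what the
  estimator estimates.** The shoulder is a multiplicative log-normal
  bump on P(s). For such a bump the maximum of d log P / d log s falls
  a factor of ~10^(u·σ) *below* the bump center, with u ≈ 1.1–1.5
  depending on amplitude. The generator therefore solves for u at the
  configured amplitude and places the bump center u·σ above
  log10(loop_size), so the noise-free derivative maximum — the
  operational definition of "average loop length" in the
  derivative-maximum method — sits exactly at `loop_size`. The B/A
  ratio is unaffected by this calibration (both compartments shift by
  the same factor).
* **Trans contacts exist only as per-bin totals.** The cis/total ratio
  is their only consumer, so full trans matrices would be dead weight.
  Expected cis/total is `cis_fraction_base ± cis_offset` (+ in B, − in
  A), realized by Poisson-sampling trans totals conditional on each
  bin's sampled cis coverage.

Crossover intervals get log-uniform lengths in [5 kb, 200 kb]
(resolution heterogeneity of single-sperm maps — the motivation for the
inverse-length weighting of the crossover score), and source hotspots
are drawn without replacement with weight
`DMC1 score × gene_body_penalty^(gene-body) × ramp`, the ramp rising
linearly 0.5 → 1.5 along each chromosome to mimic pericentromeric
crossover depletion on acrocentric chromosomes.

What the generator does *not* emulate: polymer/loop-extrusion physics,
read-level artifacts, haplotypes, translocations, mappability gaps, or
any correlation structure among ChIP-seq tracks beyond their dependence
on the shared state/compartment labels. Passing recovery tests on this
generator therefore demonstrates the estimators' correctness and
calibration under a known truth — not their robustness to every
pathology of real data.

# Numerical choices

* **Compartment calling.** Each 10-Mb chunk is observed/expected
  normalized per diagonal (means over valid pairs), clipped at the
  99.9th percentile (sparse long-range counts otherwise inject extreme
  O/E spikes), lightly box-smoothed, and the leading eigenvector of the
  column correlation matrix is extracted by power iteration with a
  deterministic initialization. Chunks shorter than 2 Mb merge into the
  previous chunk; chunks with fewer than 20 valid bins return missing
  values. Sign is oriented per chunk against an activity reference
  (promoter + gene-body state coverage by default), and each chunk is
  scaled to unit variance — no cross-chunk rescaling beyond that.
* **Insulation.** Diamond window (default 100 kb) strictly spanning the
  bin: pairs (i, j) with i ∈ [b−w, b−1], j ∈ [b+1, b+w]; the mean over
  valid cells is referenced to the chromosome mean, so the score is
  scale-invariant. Bins within one window of a chromosome end are
  missing.
* **P(s).** Log-spaced distance bins with edge ratio 1.12; each bin's
  effective separation is the pair-weighted geometric mean of the
  integer separations it actually contains — with the naive edge
  midpoint, the discrete binning leaves a deterministic sawtooth in the
  derivative even for an exact power law. The derivative is taken by
  central differences after a 5-bin moving average of log10 P, and a
  local maximum must rise at least 0.1 derivative units above its
  flanking minima to count as a loop shoulder (residual binning wobble
  is a few hundredths; genuine shoulders rise by several tenths). Ties
  between equal maxima resolve to the smaller distance. Distance bins
  with fewer than 100 kept pairs are missing.
* **Crossover score.** 1/k mass per intersected bin (k in bins, not bp)
  keeps every crossover's total contribution equal to one, giving exact
  mass conservation; the bp-length alternative is available behind
  `weight = "bp"`. The normalizing median is taken over nonzero bins
  because the genome-wide median of a sparse map is zero.
* **Quartiles and enrichment.** Descending sort with (chromosome,
  start) tie-break; top/bottom are floor(n/4) each. Enrichment is log2
  of the group mean over the genome-wide median across valid bins
  (mean-referenced, flagged, when the median is zero), significance by
  two-sided Wilcoxon rank-sum with Bonferroni multiplication by the
  number of variables, flagged at adjusted p < 0.01. Log-fold values
  are undefined (NA) for signed variables with non-positive means.
* **Pileups.** Windows are symmetrized per site (sites are unoriented);
  contact windows are divided by the chromosome's expected-by-distance
  profile before averaging, which makes the pileup of a distance-only
  matrix identically 1 — the identity test the suite runs. Confidence
  intervals are percentile bootstrap over sites (default 1000
  resamples, seeded; per-site symmetrization, which matters for CIs
  though not for the mean).
* **Models.** Two columns per variable (local value; mean over the
  101-bin ≈ 505-kb window, chosen bin-symmetric around the site);
  standardized; rows with missing features dropped and counted. PCA by
  SVD with the largest-magnitude loading element forced positive.
  Forward selection enters the smallest-p candidate while
  p < 0.001/n-candidates, skipping rank-deficient entries; adjustment
  covariates (upstream binding score, chromosomal position) compete in
  selection rather than being forced in — position is informative
  precisely because it may or may not be selected. Naive baselines:
  PRDM9 score only (DSB model); DMC1 score + position (crossover
  model); PRDM9 score + position (PRDM9-to-crossover model). Responses
  are left unstandardized.
* **Seeding.** One user seed fans out to every stochastic step through
  `derive_seed(seed, tag)` (a small exact-in-doubles string hash), so
  stages are independently reproducible and `run_all()` is bitwise
  deterministic, including bootstrap CIs.

# Design choices that were genuinely open

* **Compartments for P(s) masking come from the interphase-strength
  (ES) map**, which is also the map on which label-recovery is
  assessed: meiotic maps are generated with attenuated checkerboard
  contrast, and the pipeline mirrors the practice of defining
  compartments on the best-structured dataset, then masking all maps
  with those labels. Loop-length recovery tests mask with the
  generator's known labels, isolating the loop estimator from
  compartment-calling error (which is assessed separately).
* **Pooled versus per-chromosome curves.** The threefold loop-length
  contrast is computed on the pooled genome-wide masked curve;
  `ps_curve(per_chrom = TRUE)` exposes the per-chromosome variant since
  the averaging domain is a free choice.
* **Peak "centers"** are narrowPeak summits when a summit column is
  present, else interval midpoints (floor of (start+end)/2), with the
  half-open convention sending a boundary center to the right-hand bin.
* **Unscored BED features** are consumed as coverage fractions (not
  counts) when used as per-bin signal.
* **Crossover interval weighting** uses bin counts (see above);
  likewise the normalization median excludes zeros. Both alternatives
  are implemented behind flags so either convention can be reproduced.
* **The zygonema-specific local cis/total dip at PRDM9 sites** has no
  established magnitude, so the generator exposes it as an optional
  `zygo_dip` parameter defaulting to off rather than asserting a value.

# Problem sizes used by the tests

The suite runs the default three-chromosome, 60-Mb, 5e6-contacts
genome for end-to-end checks (label recovery, loop-ratio recovery over
ten fresh genomes, bitwise determinism of two full pipeline runs) and
small dense toys (≤ 200 bins) wherever an exact brute-force oracle is
the comparison. Statistical calibration uses 1000 null replicates for
the enrichment flag rate and 100 replicates each for null and planted
forward-selection runs. These sizes were chosen so the whole suite
exercises every operation at full default conditions while remaining
comfortable on a single CPU.

# Known limitations

* The FIRE score is a z-scored near-cis statistic, not a reimplementation
  of HiCNormCis regression; rankings agree with the concept but absolute
  values are not comparable with FIREcaller output.
* Compartment scores at 5-kb resolution from ~5e6 contacts per
  chromosome are noisy at the single-bin level; the fine-grain
  eigenvector recovers labels at r ≈ 0.9 under the default conditions,
  and worse on the attenuated meiotic-stage maps, exactly as the
  chunked method's motivation predicts.
* Balanced matrices are assumed as input; `balance_matrix()` is a plain
  ICE-style fallback (50 iterations, variance tolerance 1e-5) for raw
  triplets, not a replacement for a production balancer.
* Enrichment log-fold values for signed scores (compartment, insulation,
  FIRE) are reported against the genome median but can be NA when group
  means are non-positive; the rank-sum significance column does not
  suffer from this and is the robust comparison.
* P-values from forward selection are entry p-values, not
  post-selection-corrected inference; the Bonferroni entry threshold
  controls selection, and the reported R² gain over the naive baseline
  is the headline quantity.
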