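---
title: "Models and methods behind tnbarseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnbarseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions of the package, in the order the pipeline runs them. It states
no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## 1. Barcode and host extraction

A read from a construct-primed mapping library has the layout
`[prefix] barcode [spacer] anchor host`, where the anchor is the fixed end
sequence of the transposon/construct (default: the 15-bp Tn5 mosaic end
`GTGTATAAGAGACAG`) and the barcode is a fixed-length random tag (default
17 bp). Extraction scans each read for the **leftmost** occurrence of the
anchor tolerating up to `max_anchor_mismatches` substitutions (default 2);
reads with no forward match are re-scanned as their reverse complement,
first success wins.

Design choices, made where the experimental protocol does not dictate
one:

* **Substitutions only, no indels.** Sequencing errors on Illumina-style
  data are dominated by substitutions; a pure Hamming scan is
  deterministic, fast and keeps the leftmost-match rule unambiguous. The
  budget of 2 on a 15-bp anchor keeps the false-anchor probability per
  offset below ~10⁻⁴.
* **Leftmost match wins** for reproducibility when several offsets
  satisfy the budget. Note one consequence: raising the mismatch budget
  can, in principle, create a spurious earlier match and shift the
  reported offset; detection itself is monotone in the budget.
* **Barcodes containing N are discarded** before tallying — an ambiguous
  base has no well-defined edit distance to its neighbours and would
  corrupt merging.

The barcode is absent (not an error) when the anchor is missing or fewer
than `barcode_length` bases precede it; such reads are only counted in the
run statistics.

## 2. Library mapping

Host junction sequences of at least `min_host_len = 20` bp are placed on
the reference. Two aligners sit behind the same interface: external
`blastn` (tabular output, the default when on `PATH`) and a built-in
seed-and-verify exact matcher over both strands (seeds the first 20 bp via
Aho–Corasick matching, verifies the full host, scores 2 bits/base). The
exact matcher is the package's own full implementation for clean reads —
it requires a perfect full-length match, so with error-containing reads it
recovers a barcode only through its error-free reads (at depth 50 and 1 %
error this still recovers ≥ 99 % of barcodes; the test suite checks this).

Conventions the mapping step fixes:

* **Junction coordinate**: the 1-based reference position of the first
  host base adjacent to the construct. For minus-strand placements this is
  the *rightmost* reference coordinate of the alignment.
* **Best-bitscore filter**: per host, only hits sharing the maximal
  bitscore survive; a host with several tied locations is *ambiguous*.
* **Primary-location rule**: per barcode, candidate sites within ±5 bp
  (same chromosome and strand) collapse onto the most-supported position —
  junction jitter only arises from alignment end clipping, so a small,
  configurable radius suffices. The primary site is the collapsed site
  with maximal read support; reads from ambiguous hosts count only in the
  denominator, which conservatively removes repeat-region insertions. A
  barcode is kept iff `primary_fraction ≥ 0.75` (the boundary is kept).
* **Same-site merging**: barcodes at the same collapsed site within
  Levenshtein distance `< 2` merge into the more abundant one (ties broken
  lexicographically by sequence), conserving total reads. Processing in
  descending abundance makes the outcome order-independent; the test suite
  cross-checks it against a brute-force all-pairs dynamic-programming
  clustering oracle.
* **Annotation**: insertions inside a feature report an insertion
  percentile measured from the feature's own 5′ end
  (`100·(site − start + 1)/length` on `+`, `100·(end − site + 1)/length`
  on `−`); intergenic insertions report the nearest feature with a signed
  distance (negative 5′ of the feature start in genome coordinates) and no
  percentile.

## 3. Counting and merging

Counting tallies extracted barcodes per sample. Merging of sequencing
variants has two regimes:

* **Map-guided** (a library map is supplied): a counted barcode within
  distance `< 2` of *exactly one* mapped barcode is absorbed into it — the
  mapped sequence is trusted even when the variant is more abundant. A
  barcode within range of several mapped barcodes is left untouched:
  misassigning reads between two real strains is worse than keeping an
  orphan row. Unmapped barcodes are retained (un-annotated) rather than
  dropped, which the isogenic-lineage use case requires.
* **De novo**: greedy by descending abundance with lexicographic
  tie-breaks, the more abundant barcode absorbing the rarer.

Counts are conserved in both regimes. `merge_samples` outer-joins samples
with zero fill; `barcode_frequencies` divides each sample by its total for
lineage-trajectory work.

## 4. Selection analysis

### Size factors

Median-of-ratios: the reference pseudo-sample is the per-barcode geometric
mean over samples (barcodes with any zero excluded from the reference);
`s_j = median_i(c_ij / ref_i)`. With spiked wild-type controls the median
runs over control barcodes only, which anchors normalization to strains of
known neutral fitness — under a population bottleneck most of the library
shifts and the global median is biased, but the controls are not. Factors
are rescaled to geometric mean 1, which makes normalization idempotent
(re-deriving factors from a normalized matrix returns 1) without changing
any between-sample ratio.

### Control-barcode QC

Before anything else, each sample is regressed: `log10(count + 1)` on
`log10(concentration)` over the wild-type control dilution series, on
**raw** counts — QC gates samples before they can influence size factors.
Samples with `r² ≤ 0.8` are dropped from both normalization and testing.
At least 4 wild-type control barcodes are required; with fewer, QC is
skipped with a warning and all samples kept. A constant response has zero
explained and zero total variance; its `r²` is defined as 0 (an undefined
ratio would otherwise propagate `NaN`).

### Mean–variance model

Across control-condition replicates (the condition assumed to carry no
treatment effect, hence the clean estimate of technical + biological
noise), each barcode contributes an empirical mean `μ_i` and variance
`v_i`. Over barcodes with `v_i > μ_i` the model
`σ²(μ) = μ + exp(b)·μ^k` is fitted by OLS of `log(v_i − μ_i)` on
`log(μ_i)`. The fit falls back to Poisson (`σ² = μ`) in three cases:
a single replicate; fewer than 10 overdispersed barcodes; or a pooled
chi-square dispersion test (`Σ (r−1)·v_i/μ_i` against its Poisson null) at
p > 0.05. The last guard exists because for genuinely Poisson replicates
about half of all barcodes satisfy `v > μ` by chance, so the existence of
such barcodes is not evidence of overdispersion — without the guard the
regression would fit pure noise and report a spurious dispersion.

### Barcode test

Each barcode's treatment mean `T` (mean normalized count over treatment
replicates) is referred to a negative-binomial null centred on the control
mean `μ̂` with variance `σ²(μ̂)` from the model
(`size = μ̂²/(σ² − μ̂)`; Poisson when `σ² ≤ μ̂`):
`p_neg = P(X ≤ ⌊T⌋)`, `p_pos = P(X ≥ ⌈T⌉)`. The discrete floors/ceilings
make the two one-sided p-values complementary with the usual point mass
(`p_neg + p_pos ≥ 1`). `LFC = log2((T + 1)/(μ̂ + 1))` with pseudocount 1.
Barcodes with zero mean in both conditions are excluded; percentile ranks
`u = rank(p)/n` (average ties) are computed per direction over all tested
barcodes.

### Gene ranking (α-RRA)

For a gene with sorted member ranks `u_(1) ≤ … ≤ u_(m)`, only *good*
barcodes (direction p-value < α, default α = 0.05) enter the score:
`ρ = min over good k of P(Beta(k, m−k+1) ≤ u_(k))`; genes with no good
barcode get `ρ = 1`. Significance comes from a permutation null built per
gene size by randomly reassigning barcodes (with their ranks and good
flags) to genes, `p = (1 + #{ρ_null ≤ ρ_obs})/(1 + n_perm)`, BH-adjusted
per direction. The gene LFC is the median member LFC.

Two properties of this construction are worth stating explicitly because
they shape what "calibrated" means here:

* Genes with no good barcode receive `p = 1`. Under a global null with
  `m = 3` and α = 0.05, about `0.95³ ≈ 86 %` of genes land there, so the
  null distribution of gene p-values is a uniform *continuous part* plus a
  large atom at 1. The p-values are valid (super-uniform,
  `P(p ≤ t) ≤ t` for every t) — which is the property that controls
  type-I error — but a blanket Kolmogorov–Smirnov test against U(0,1)
  over all genes will reject on the atom by construction. The package's
  null-calibration test therefore checks super-uniformity at several
  thresholds plus exact uniformity of the continuous part.
* `ρ` is monotone in the member ranks within the regime the pipeline
  produces (goodness ⇔ small rank, so good members form a prefix of the
  sorted ranks). For arbitrary good/bad patterns monotonicity can fail;
  such patterns cannot arise from the rank-based good definition.

**Permutation resolution.** The smallest achievable permutation p-value is
`1/(n_perm + 1)`. With 1000 permutations and 1000 genes, 20 genuine hits
sit exactly at BH-FDR ≈ 0.05 on granularity alone, so screen-scale
analyses (and the acceptance script) use `n_perm = 10000` — the usual
rank-aggregation convention of scaling permutation rounds with the number
of genes (~10×). The function default stays at 1000, which is adequate for
small panels.

Determinism: for a fixed seed the permutation null, and hence the entire
results CSV, is byte-identical across runs.

## 5. What the simulator emulates — and what it does not

`sim_genome`/`sim_library`/`sim_mapping_reads`/`sim_screen` generate, under
a single seed: a random genome with non-overlapping annotated genes
(optionally an exact duplicated segment, to exercise multimap removal);
uniform insertion sites with unique barcodes at pairwise distance ≥ 3
(optionally planted distance-1 collision pairs, to exercise merging);
construct-layout mapping reads with substitution errors and random
orientation; and screen count matrices with Dirichlet(1) baseline
abundances, gene effects `2^LFC` broadcast to member barcodes with
Normal(0, 0.2) per-barcode jitter in log2 (different insertion points in
the same gene rarely have identical effects — the jitter makes rank
aggregation earn its keep), NB counts with `σ² = μ + φ·μ²` (default
φ = 0.1, a typical mid-range overdispersion for amplicon screens), an
optional multinomial bottleneck in treatment samples, and wild-type
control barcodes spiked at a fixed 5 % of the population split by their
stated concentrations.

Not emulated, deliberately: quality-score-dependent error profiles,
indels, PCR chimeras and index hopping, GC/length amplification bias, and
positional fitness effects within a gene beyond the log-normal jitter.
Passing tests on simulated data therefore demonstrate the correctness of
the algorithms under the stated noise model, not robustness to every
artifact of real libraries.

## 6. Problem sizes used by tests and the acceptance script

Chosen as the smallest sizes at which each property is statistically
meaningful: mapping round-trips use a 200-kb genome, 150 genes,
100 insertions at depth 30 (error-free) and 50 (1 % error);
mean–variance recovery uses 5000 barcodes × 50 replicates (replicate
variance estimates at 3 replicates carry a log-scale bias that 50
replicates remove); null calibration and spike-in power use 1000 genes ×
3 barcodes, 3 vs 3 replicates at depth 10⁶ with 10⁴ permutations;
merge-oracle equivalence uses 200 random instances of ≤ 20 barcodes.

## 7. Known limitations

Two-condition comparisons only (multi-condition designs run pairwise); no
paired designs, batch covariates or time-course models; no essentiality
calling from insertion density; no UMI handling; the exact fallback
aligner ignores hosts whose every read carries an error (use `blastn` for
degraded data); `adist`-based merging is quadratic in the number of
distinct barcodes and is intended for libraries up to a few tens of
thousands of barcodes per site group.
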