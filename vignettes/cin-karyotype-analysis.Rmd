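---
title: "Calling karyotypes and copy-number interactions in CIN populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling karyotypes and copy-number interactions in CIN populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyocin)
```

## The problem

Populations with chromosomal instability (CIN) — budding yeast carrying
kinetochore error-correction mutants, or tumors — missegregate chromosomes at
rates of roughly 0.5–5% per chromosome per division. Under selection, such
populations rapidly accumulate *complex aneuploid karyotypes*: combinations of
whole-chromosome gains and losses. Which combinations survive is not random;
specific chromosome pairs co-occur more or less often than independence
predicts, reflecting positive and negative fitness interactions between
aneuploidies (chromosome copy-number interactions, CCNIs).

`karyocin` implements the computational side of this analysis end to end:

1. whole-chromosome copy-number calling from read-depth profiles,
2. cohort statistics — aneuploidy frequencies, DNA-content-change burden,
   pooled karyotype SD, pairwise copy-number correlations and hypergeometric
   co-occurrence tests,
3. CCNI scoring from double-disome colony-size matrices,
4. arm-level karyotypes from tumor copy-number segment tables,
5. synthetic-data generators, including a Wright–Fisher serial-passaging
   simulator, so every step is testable without sequencing data.

## Copy-number calling from read depth

For each chromosome the caller counts reads whose *midpoint* falls inside the
telomere-trimmed chromosome body, `[E, L - E)` with `E = 15` kb by default.
Midpoint assignment is unambiguous and count-conserving; the terminal windows
are excluded because subtelomeric repeats map poorly and bias densities. (The
window can be inverted with `subtelomeres_only = TRUE` for diagnostics.)

Density is `reads / usable length`. Chromosomes are then ranked by density
and the *second-lowest quartile* — rank positions `ceiling(C/4) < r <=
ceiling(C/2)`, ties broken by chromosome order — defines the euploid baseline
(arithmetic mean of their densities; a median variant is available via
`baseline_stat = "median"`). This baseline is robust both to gained
chromosomes, which occupy the top ranks, and to an occasional poorly covered
chromosome at the bottom. Copy number is `ploidy * density / baseline`.

Integer calls round to the nearest integer with exact `.5` values rounded
*away from the basal ploidy* (1.5 → 2 in haploids; 1.5 → 1 and 2.5 → 3 in
diploids), so borderline chromosomes are called aneuploid rather than
silently normalized. Nullisomy calls are emitted with a warning: copy 0 is
lethal in vivo, so such a call almost always indicates a normalization
problem.

**Assumption and failure mode.** The baseline-quartile rule assumes at least
half the chromosomes sit at the basal copy number. In cohorts simulated with
very permissive fitness landscapes (many drift-accumulated gains), strains
whose baseline quartile is contaminated by disomes are mis-normalized — copy
estimates shift down by up to a factor of two and euploid chromosomes can be
called nullisomic. This is a property of the published normalization, not of
this implementation; `analysis/02_call_karyotypes.R` reports the recovery
rate on the simulated cohort so the effect is visible.

## Co-occurrence statistics

For two aneuploidy events held by `K` and `n` of `N` strains with overlap
`k`, the significance statistic is the hypergeometric *point probability*

$$P(X = k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

computed in log space via `lchoose` so values down to ~1e-300 remain exact.
The point statistic (rather than a cumulative tail) is used because it is the
named pmf the original analyses report; a tail variant
(`hypergeometric_tail`, lower tail for exclusivity, upper for enrichment) is
available via `stat = "tail"` in `pairwise_cooccurrence()`. Direction is the
sign of `k - nK/N`. No multiple-testing correction is applied; published
practice compares raw values against fixed thresholds (0.001, 0.05, 5e-7
depending on cohort), which are left to the caller.

Events are direction-specific: diploid cohorts distinguish `chr:gain`
(copy > 2) from `chr:loss` (copy < 2); haploid cohorts use gain-only events
by default since losses are lethal.

Correlation heatmap values (`copy_correlation_matrix`) use *continuous* copy
estimates across strains, while the significance tests use binarized calls —
mirroring how the two are presented in this field. Pairs where either
chromosome shows no aneuploidy, or has constant values, are flagged
not-included.

The DNA-content-change burden of a karyotype is
`100 * sum(|c_i - p| * f_i) / p`, the absolute copy deviation weighted by
each chromosome's genome fraction and normalized to the ploidy, so haploid
and diploid burdens are comparable. The pooled karyotype SD is the square
root of the mean per-chromosome sample variance of copy values; a
per-chromosome (rather than per-strain) pooling was chosen because karyotype
convergence is a per-chromosome phenomenon, and the definition is stated
here because it is not standardized.

## CCNI scoring from colony sizes

Double-disome colony sizes confound single-disome costs and marker effects
with the pairwise interaction. `normalize_colony_matrix()` removes row and
column effects multiplicatively:

$$\mathrm{rel}[a,b] = M[a,b] \cdot \frac{G}{R_a \, C_b}$$

with `R`, `C`, `G` the arithmetic row, column and grand means over present
cells (`stat = "median"` substitutes medians). On a complete interaction-free
(rank-1) matrix this is exactly 1 everywhere, so marker- or plate-specific
multiplicative effects cannot create spurious interactions. Two caveats are
inherent to the arithmetic scheme and worth knowing:

- With *missing cells* (the diagonal — the same chromosome cannot be disomic
  twice — or unscored combinations) the rank-1 cancellation is approximate,
  not exact.
- The interaction cell contaminates its own row/column means, so a strong
  planted interaction is shrunk toward 1 (a planted 0.4 in an 8×8 matrix
  recovers as ≈ 0.46 even noise-free). Rank order across pairs is preserved,
  which is what downstream comparisons use.

A CCNI score is the mean of the two marker orientations (`rel[a,b]` and
`rel[b,a]`); single-orientation pairs are flagged. Scores below 1 indicate
negative interactions. `correlate_ccni_with_cooccurrence()` compares scores
with cohort copy-number correlations by Pearson correlation, with the
two-tailed p-value from the t distribution on `pairs - 2` degrees of freedom
(via `cor.test`).

## Arm-level tumor karyotypes

Segment tables (SEG dialect: header plus Sample/Chromosome/Start/End/
Segment_Mean) are normalized to 0-based half-open coordinates and `chr`-less
chromosome keys. Segment values are treated as log2(copy/2) ratios, the
common CNV-file convention. Arm intervals come from a cytoband file (p/q band
unions, `acen` bands excluded; acrocentric chromosomes get q-arms only).

Per sample × arm, the profile records the length-weighted mean and the
length-weighted median (the value at 50% cumulative overlap, taking the
*lower* value at an exact boundary) of intersecting segment values. Their
gap flags arms whose level is driven by a large focal event rather than a
whole-arm change; samples with any gap strictly above 0.2 are excluded.
Calls are +1/−1 when the weighted mean is at or beyond ±0.2 (inclusive;
the threshold is not published and is configurable — ±0.2 was chosen
symmetric with the exclusion gap), samples with fewer than two aberrant arms
are dropped as non-complex, and the display filter keeps arms aberrant in
strictly more than 10% of samples. The retained calls feed the same
co-occurrence machinery as the yeast cohorts.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with the
statistical structure the analyses assume — they are the package's test bed,
not a model of missegregation mechanism.

`simulate_adaptation()` emulates serial single-colony passaging: a
Wright–Fisher population (default 200 cells) evolves for 10 rounds × 20
generations (~200 generations through 10 clonal expansions, the published
regimen); each generation offspring are sampled proportional to
`count × fitness`, each chromosome of each daughter gains or loses one copy
with probability m/2 each (default m = 0.01, inside the 0.5–4.2% per-division
range measured for adapted CIN strains), and each round ends with a
bottleneck to a single clone sampled by frequency — the colony-picking proxy.
Fitness is multiplicative: per-chromosome copy-state factors `s_i(c_i)`
(copy 0 lethal in haploids by default) times pairwise terms
`eps_ij(c_i, c_j)`; all are configuration values, none hard-coded. Copy
numbers move in steps of one, matching observed disomy/trisomy progression,
and are capped (default 4). One root seed deterministically derives
per-replicate streams, so cohorts are pure functions of (config, seed). The
per-generation update is compiled (Rcpp) and uses R's RNG, keeping results
seed-reproducible; an R implementation of the fitness model
(`karyotype_fitness`) cross-checks the compiled core in the tests. Extinct
replicates (possible with lethal states) are resampled up to a retry cap and
counted.

What the simulator does *not* emulate: mechanistic missegregation biology
(no chromosome-size-dependent rates, no whole-genome doubling), mutation of
point variants, and within-colony spatial structure. Passing tests therefore
show that the statistics recover planted structure under the model's
assumptions — not that real cohorts satisfy those assumptions.

`simulate_read_counts()` draws per-chromosome Poisson counts with mean
`depth × length × copy / ploidy` and uniform start positions (50 bp reads by
default). `simulate_colony_matrix()` builds
`base · g_a · g_b · eps_ab · lognormal noise` with a missing diagonal.
`simulate_segment_tables()` writes SEG files with per-arm levels
`log2((2 + call)/2)`, 1–5 random segment pieces, Gaussian segment noise, and
optional short high-amplitude focal segments to exercise the mean–median
exclusion.

## Problem sizes and numerical choices

- Read-simulation studies (tests and `analysis/02`) use a 1:50 scaled yeast
  genome (16 chromosomes, sacCer3-proportional lengths, telomere exclusion
  scaled to 300 bp) at 30× equivalent depth; calling accuracy only improves
  with chromosome length, so the scaled results are conservative.
- Exclusivity-recovery studies use 100 replicate cohorts of 100 strains at
  the full passaging regimen, with s = 1.3 for two beneficial gains and a
  pairwise penalty eps = 0.5.
- Hypergeometric probabilities are validated against exhaustive subset
  enumeration for small cohorts and against sum-to-one over the support up
  to N = 200 at 1e-12.
- Ties: baseline-quartile ranking breaks density ties by chromosome order;
  the weighted median takes the lower value at an exact 50% boundary; arm
  call thresholds are inclusive, the gap and display filters strictly
  exclusive — all boundary behaviors are asserted in the tests.
- qPCR copy numbers average duplicate C_t values first, then
  `ΔC_t = target − reference primer` per strain, fold = `2^(−ΔC_t)`, and
  copy = `ploidy × fold(test)/fold(wild type)`. Because a per-strain plate
  offset cancels in ΔC_t and a per-primer offset cancels in the strain
  ratio, the two possible orderings of the double normalization give
  identical copy numbers.
- `doubling_time()` fits ln(OD) against time by least squares over all
  points (no outlier rejection) and reports `ln 2 / slope` with the fit R².

## Known limitations

- The caller estimates whole-chromosome copies only; segmental yeast
  aneuploidies masquerade as intermediate copy values.
- The second-lowest-quartile baseline fails informatively (nullisomy
  warnings) when fewer than half the chromosomes are euploid.
- Colony-size normalization is biased toward 1 for strong interactions (see
  above); interpret scores comparatively, not as calibrated fitness ratios.
- The tumor module analyzes whatever cohort it is given; cancer-type
  selection and purity/ploidy correction are out of scope.
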