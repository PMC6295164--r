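# karyocin

Analysis of complex aneuploid karyotypes in chromosomally unstable (CIN)
populations: whole-chromosome copy-number calling from read depth, cohort
co-occurrence statistics, colony-size interaction scoring, and arm-level
tumor karyotypes — plus the synthetic-data generators needed to exercise all
of it without external data.

## Who this is for

Yeast populations with high chromosome-missegregation rates (e.g. chromosomal
passenger complex mutants) adapt by accumulating specific combinations of
whole-chromosome gains and losses. Which combinations arise is shaped by
*chromosome copy-number interactions* (CCNIs): pairwise fitness effects
between aneuploidies beyond their individual costs and benefits. The same
question — which copy-number changes co-occur and which exclude each other —
applies to arm-level somatic copy-number alterations in tumors. This package
is for people analysing such cohorts: karyotype matrices in, interaction
statistics out.

## The statistics at the core

- **Copy calling.** Reads are assigned to chromosomes by midpoint, the 15 kb
  nearest each telomere is excluded, density = count / usable length, and the
  mean density of the *second-lowest quartile* of chromosomes is the euploid
  baseline: `c_i = p * density_i / baseline`. Integer calls round `.5` away
  from the basal ploidy `p`.
- **Co-occurrence.** For events held by `K` and `n` of `N` strains with
  overlap `k`, significance is the hypergeometric point probability
  `P(X = k) = C(K,k) C(N−K,n−k) / C(N,n)` (log-space exact), with direction
  from the sign of `k − nK/N`.
- **Burden.** DNA-content change of a karyotype:
  `100 * Σ_i |c_i − p| f_i / p`, with `f_i` the genome fraction of
  chromosome i.
- **CCNI score.** Colony sizes of double disomes are normalized as
  `rel[a,b] = M[a,b] · G / (R_a C_b)` (row/column/grand means), and the score
  of a pair is the mean of its two marker orientations; < 1 means a negative
  interaction.
- **Tumor arms.** Length-weighted mean and median of segment values per
  chromosome arm; samples are excluded when any arm's mean–median gap
  exceeds 0.2 (large focal events), calls are ±1 at |mean| ≥ 0.2, and
  non-complex karyotypes (< 2 aberrant arms) are dropped.

The Wright–Fisher passaging simulator (`simulate_adaptation`) generates
cohorts under configurable per-copy-state fitness and pairwise interaction
terms, with per-chromosome missegregation (default 1% per division) and a
colony-picking bottleneck each round.

## Worked example

Call a karyotype from simulated ~30x reads (disomies of chromosomes III and
VIII planted on a 1:50 scaled yeast genome), then test a simulated cohort for
mutual exclusivity between two beneficial gains with a planted fitness
penalty:

```r
library(karyocin)

genome <- yeast_genome(basal_ploidy = 1, scale = 0.02)
planted <- rep(1L, 16); planted[c(3, 8)] <- 2L
reads <- simulate_read_counts(planted, genome, depth = 0.6, seed = 7)
kt <- call_karyotype(reads, genome)
kt[kt$aneuploid, ]
#>     chrom read_count usable_length density copy integer_copy aneuploid
#> 3  chrIII       7002          5732    1.22 2.02            2      TRUE
#> 8 chrVIII      12601         10653    1.18 1.95            2      TRUE

cfg <- simulation_config(yeast_genome(1))          # 10 rounds x 20 generations
cfg <- set_copy_fitness(cfg, "chrVIII", 2, 1.3)    # beneficial disomy
cfg <- set_copy_fitness(cfg, "chrX", 2, 1.3)       # beneficial disomy
cfg <- add_interaction(cfg, "chrVIII", 2, "chrX", 2, 0.5)  # negative CCNI
cohort <- simulate_adaptation(cfg, replicates = 100, seed = 1)
co <- pairwise_cooccurrence(cohort$karyotypes, ploidy = 1)
co[co$event_a == "chrVIII:gain" & co$event_b == "chrX:gain", ]
#>         event_a   event_b   N  K  n  k expected   direction        p
#> 86 chrVIII:gain chrX:gain 100 57 63 21     35.9 exclusivity 2.68e-11
```

Both planted disomies are recovered (copies 2.02 and 1.95 round to 2), and
the planted penalty surfaces as mutual exclusivity: 21 strains carry both
gains where independence predicts ~36, with a point probability of 3e-11.

## The analysis workflow

`analysis/` contains the numbered drivers for a full study on synthetic
data; each writes its tables under `results/`:

1. `01_simulate_cohort.R` — 102 haploid strains adapted under a landscape
   with one near-essential gain, several beneficial disomies and negative
   interactions between redundant gains.
2. `02_call_karyotypes.R` — regenerates every strain's karyotype from
   simulated ~30x reads and reports recovery.
3. `03_cooccurrence.R` — pairwise hypergeometric tests and the copy-number
   correlation matrix.
4. `04_interactions.R` — colony-size CCNI scores and their correlation with
   the cohort's copy-number correlations.
5. `05_tumor_arms.R` — arm-level analysis of a synthetic tumor SEG cohort
   with planted exclusive classes and focal-event contamination.

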