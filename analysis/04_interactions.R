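#!/usr/bin/env Rscript
# Score chromosome copy-number interactions (CCNIs) from a double-disome
# colony-size experiment simulated with the same interaction structure the
# cohort evolved under, then ask whether CCNI scores predict which
# aneuploidies co-occur in the adapted cohort.

suppressPackageStartupMessages(library(karyocin))
dir.create("results", showWarnings = FALSE)

# single-disome fitness effects and pairwise terms mirror the landscape in
# 01_simulate_cohort.R (colony size tracks relative fitness)
chroms <- c("chrI", "chrIII", "chrVIII", "chrX", "chrXII", "chrXV")
g <- c(chrI = 1.05, chrIII = 1.25, chrVIII = 1.25, chrX = 1.20,
       chrXII = 0.95, chrXV = 0.95)
eps <- matrix(1, 6, 6, dimnames = list(chroms, chroms))
eps["chrVIII", "chrX"] <- eps["chrX", "chrVIII"] <- 0.5
eps["chrIII", "chrX"] <- eps["chrX", "chrIII"] <- 0.7
eps["chrIII", "chrVIII"] <- eps["chrVIII", "chrIII"] <- 1.15

colony <- simulate_colony_matrix(g, eps, base = 4, noise_sigma = 0.08,
                                 seed = 77)
write_colony_matrix(colony, "results/colony_sizes.tsv")

rel <- normalize_colony_matrix(colony)
write_colony_matrix(rel, "results/colony_relative_fitness.tsv")

scores <- ccni_scores(rel)
write.table(scores, "results/ccni_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("CCNI scores (score < 1 = negative interaction):\n")
for (i in order(scores$score))
  cat(sprintf("  %s-%s: %.2f\n", scores$chrom_a[i], scores$chrom_b[i],
              scores$score[i]))

corr <- read.table("results/copy_correlations.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
res <- correlate_ccni_with_cooccurrence(scores, corr)
cat(sprintf("CCNI vs cohort correlation over %d shared pairs: r = %.2f, two-tailed p = %.3g\n",
            res$n_pairs, res$r, res$p))
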