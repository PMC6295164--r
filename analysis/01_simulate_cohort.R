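#!/usr/bin/env Rscript
# Simulate a cohort of 102 haploid CIN-adapted strains under a fitness
# landscape with one near-essential gain (chr2), several beneficial gains,
# and negative interactions between redundant gains, then summarize the
# aneuploidy structure of the cohort.

suppressPackageStartupMessages(library(karyocin))
dir.create("results", showWarnings = FALSE)

genome <- yeast_genome(basal_ploidy = 1)

cfg <- simulation_config(genome)  # 10 expansions x 20 generations, m = 0.01
# aneuploidy is generally costly: mild fitness penalty per extra copy unless
# a specific gain is beneficial (overridden below)
for (ch in genome$chrom) {
  cfg <- set_copy_fitness(cfg, ch, 2, 0.95)
  cfg <- set_copy_fitness(cfg, ch, 3, 0.85)
  cfg <- set_copy_fitness(cfg, ch, 4, 0.75)
}
# euploid chr2 is barely viable once CIN is induced; its gain rescues growth
cfg <- set_copy_fitness(cfg, "chrII", 1, 0.05)
cfg <- set_copy_fitness(cfg, "chrII", 2, 1.0)
# individually beneficial disomies
cfg <- set_copy_fitness(cfg, "chrIII", 2, 1.25)
cfg <- set_copy_fitness(cfg, "chrVIII", 2, 1.25)
cfg <- set_copy_fitness(cfg, "chrX", 2, 1.20)
cfg <- set_copy_fitness(cfg, "chrI", 2, 1.05)
# negative interactions between redundant gains; one mildly positive pair
cfg <- add_interaction(cfg, "chrVIII", 2, "chrX", 2, 0.5)
cfg <- add_interaction(cfg, "chrIII", 2, "chrX", 2, 0.7)
cfg <- add_interaction(cfg, "chrIII", 2, "chrVIII", 2, 1.15)

sim <- simulate_adaptation(cfg, replicates = 102, seed = 42)
write_karyotype_matrix(sim$karyotypes, "results/cohort_karyotypes.tsv")

freq <- aneuploidy_frequency(sim$karyotypes, ploidy = 1)
write.table(freq, "results/aneuploidy_frequency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

burden <- dna_content_change(sim$karyotypes, genome)
writeLines(sprintf("%s\t%.3f", rownames(sim$karyotypes), burden),
           "results/dna_content_change.tsv")

complex_frac <- mean(rowSums(sim$karyotypes != 1L) > 1)
cat(sprintf("simulated %d strains; chr2 gain frequency %.2f\n",
            nrow(sim$karyotypes), freq$frequency[freq$chrom == "chrII"]))
cat(sprintf("complex karyotypes (>1 aberration): %.0f%%\n",
            100 * complex_frac))
cat(sprintf("mean DNA-content change: %.1f%% (max %.1f%%)\n",
            mean(burden), max(burden)))
cat(sprintf("pooled karyotype SD: %.3f\n",
            karyotype_pooled_sd(sim$karyotypes)))
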