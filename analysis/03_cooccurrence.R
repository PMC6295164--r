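#!/usr/bin/env Rscript
# Cohort statistics: binarize the read-depth copy estimates, test every
# aneuploidy pair for co-occurrence/exclusivity with the hypergeometric
# point probability, and compute the continuous copy-number correlation
# matrix.

suppressPackageStartupMessages(library(karyocin))
dir.create("results", showWarnings = FALSE)

copies <- read_karyotype_matrix("results/cohort_copy_estimates.tsv")
calls <- apply(copies, 2, function(x) call_aneuploidy(x, ploidy = 1))
rownames(calls) <- rownames(copies)

co <- pairwise_cooccurrence(calls, ploidy = 1)
co <- co[order(co$p), ]
write.table(co, "results/cooccurrence_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cc <- copy_correlation_matrix(copies, ploidy = 1)
write.table(cc$pairs, "results/copy_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- co[co$p < 0.001, ]
cat(sprintf("%d event pairs tested; %d with p < 0.001:\n", nrow(co),
            nrow(sig)))
for (i in seq_len(nrow(sig)))
  cat(sprintf("  %s + %s: k=%d vs expected %.1f (%s, p=%.2g)\n",
              sig$event_a[i], sig$event_b[i], sig$k[i], sig$expected[i],
              sig$direction[i], sig$p[i]))
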