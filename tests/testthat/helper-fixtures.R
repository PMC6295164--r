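# small genomes and fixture builders shared across tests

# n equal-length chromosomes; simple and symmetric
toy_genome <- function(n = 16, len = 100000, ploidy = 1L, excl = 1000) {
  genome_build(paste0("chr", seq_len(n)), rep(len, n), ploidy, excl)
}

# 1:50 scaled yeast genome used for fast read-simulation round trips
scaled_yeast <- function(ploidy = 1L) yeast_genome(ploidy, scale = 0.02)

# noise-free read table: `per_chrom` reads evenly spaced inside the
# telomere-trimmed body of each chromosome
even_reads <- function(genome, per_chrom, read_length = 50) {
  excl <- attr(genome, "telomere_exclusion")
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    n <- if (length(per_chrom) > 1) per_chrom[i] else per_chrom
    mids <- seq(excl + 100, genome$length[i] - excl - 100, length.out = n)
    data.frame(chrom = genome$chrom[i],
               start = round(mids - read_length / 2),
               end = round(mids + read_length / 2),
               stringsAsFactors = FALSE)
  }))
}

# write lines to a temp file and return its path
tmpfile_with <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy cytoband table: each chromosome gets p [0, 4e7), acen [4e7, 6e7),
# q [6e7, 1e8)
toy_cytobands <- function(chroms = c("1", "7", "10", "19")) {
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch,
               start = c(0, 4e7, 6e7), end = c(4e7, 6e7, 1e8),
               band = c("p11", "cen", "q11"),
               stain = c("gpos", "acen", "gneg"),
               stringsAsFactors = FALSE)
  }))
}

# brute-force hypergeometric point probability by enumerating all
# subsets of size n from N, counting those overlapping the first K in k
enumerate_hypergeom <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits == k)
}
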