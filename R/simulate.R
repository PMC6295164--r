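# evaluate expr under a fixed seed, restoring the caller's RNG state after
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-replicate seed streams from one root seed
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Configuration for the CIN adaptation simulator
#'
#' Describes the generative model behind the serial single-colony passaging
#' experiment: a population of `population_size` cells evolves by
#' Wright-Fisher resampling with fitness proportional to a multiplicative
#' karyotype fitness \eqn{w = \prod_i s_i(c_i) \prod_{i<j} \epsilon_{ij}(c_i, c_j)},
#' each chromosome of each daughter gains or loses one copy with probability
#' m/2 each per division, and at the end of each round the population is
#' bottlenecked to a single clone sampled proportional to clone frequency
#' (the colony-picking proxy). Copy numbers move by steps of one and are
#' clamped to `[0, max_copy]`; copy 0 is lethal by default in haploids.
#'
#' @param genome a [genome_build()]; supplies chromosomes and basal ploidy.
#' @param missegregation_prob per-chromosome per-division missegregation
#'   probability m (gain and loss each occur with probability m/2); the
#'   default 0.01 sits inside the 0.5-4.2% per-division range measured for
#'   adapted CIN strains.
#' @param population_size cells per expansion.
#' @param rounds number of clonal-expansion/bottleneck rounds (default 10).
#' @param generations_per_round generations per round (default 20, i.e. ~200
#'   generations over 10 rounds).
#' @param max_copy largest copy number a chromosome can reach.
#' @param copy_zero_lethal fitness of any copy-0 state forced to 0.
#' @param max_retries resampling attempts when a replicate goes extinct.
#' @return a `cin_config` list; adjust per-copy-state fitness with
#'   [set_copy_fitness()] and pairwise terms with [add_interaction()].
#' @export
simulation_config <- function(genome, missegregation_prob = 0.01,
                              population_size = 200, rounds = 10,
                              generations_per_round = 20, max_copy = 4,
                              copy_zero_lethal = basal_ploidy(genome) == 1,
                              max_retries = 10) {
  stopifnot(missegregation_prob >= 0, missegregation_prob <= 1,
            population_size >= 1, rounds >= 1, generations_per_round >= 1)
  C <- nrow(genome)
  fitness <- matrix(1, C, max_copy + 1,
                    dimnames = list(genome$chrom, 0:max_copy))
  if (copy_zero_lethal) fitness[, 1] <- 0
  structure(list(genome = genome,
                 ploidy = basal_ploidy(genome),
                 m = missegregation_prob,
                 fitness = fitness,
                 interactions = NULL,
                 population_size = as.integer(population_size),
                 rounds = as.integer(rounds),
                 generations_per_round = as.integer(generations_per_round),
                 max_copy = as.integer(max_copy),
                 max_retries = as.integer(max_retries)),
            class = "cin_config")
}

#' Set the fitness factor of a chromosome copy state
#' @param config a [simulation_config()].
#' @param chrom chromosome name.
#' @param copy copy number (0..max_copy).
#' @param factor multiplicative fitness factor (> 0, or 0 = lethal).
#' @return the updated config.
#' @export
set_copy_fitness <- function(config, chrom, copy, factor) {
  stopifnot(inherits(config, "cin_config"), factor >= 0)
  config$fitness[chrom, as.character(copy)] <- factor
  config
}

#' Add a pairwise copy-state interaction term
#'
#' Multiplies the fitness of any karyotype where `chrom_a` is at `copy_a`
#' and `chrom_b` at `copy_b` by `factor` (a chromosome copy-number
#' interaction: < 1 negative, > 1 positive).
#'
#' @inheritParams set_copy_fitness
#' @param chrom_a,chrom_b chromosome names.
#' @param copy_a,copy_b copy states the term applies to.
#' @export
add_interaction <- function(config, chrom_a, copy_a, chrom_b, copy_b, factor) {
  stopifnot(inherits(config, "cin_config"), factor >= 0)
  row <- data.frame(chrom_a = chrom_a, copy_a = copy_a,
                    chrom_b = chrom_b, copy_b = copy_b, factor = factor,
                    stringsAsFactors = FALSE)
  config$interactions <- rbind(config$interactions, row)
  config
}

# fitness of each clone karyotype (rows of kar) under the config; reference
# R implementation of the model the compiled simulator uses
karyotype_fitness <- function(kar, config) {
  C <- ncol(kar)
  idx <- cbind(rep(seq_len(C), each = nrow(kar)), as.vector(kar) + 1L)
  s <- matrix(config$fitness[idx], nrow(kar), C)
  w <- apply(s, 1, prod)
  if (!is.null(config$interactions)) {
    ia <- config$interactions
    a <- match(ia$chrom_a, config$genome$chrom)
    b <- match(ia$chrom_b, config$genome$chrom)
    for (r in seq_len(nrow(ia))) {
      hit <- kar[, a[r]] == ia$copy_a[r] & kar[, b[r]] == ia$copy_b[r]
      w[hit] <- w[hit] * ia$factor[r]
    }
  }
  w
}

# one replicate via the compiled Wright-Fisher core; NULL on extinction
run_one_replicate <- function(config) {
  ia <- config$interactions
  if (is.null(ia))
    ia <- data.frame(chrom_a = character(), copy_a = integer(),
                     chrom_b = character(), copy_b = integer(),
                     factor = numeric())
  lineage <- wf_replicate(config$fitness,
                          match(ia$chrom_a, config$genome$chrom) - 1L,
                          match(ia$chrom_b, config$genome$chrom) - 1L,
                          as.integer(ia$copy_a), as.integer(ia$copy_b),
                          as.numeric(ia$factor),
                          config$m, config$population_size, config$rounds,
                          config$generations_per_round, config$max_copy,
                          config$ploidy)
  if (nrow(lineage) == 0) return(NULL)
  colnames(lineage) <- config$genome$chrom
  list(karyotype = lineage[nrow(lineage), ], lineage = lineage)
}

#' Simulate a cohort of CIN-adapted strains
#'
#' Runs `replicates` independent serial-passaging simulations under the
#' configured fitness landscape; each replicate yields one adapted strain's
#' final karyotype, emulating a cohort of independently adapted clones.
#' Reproducible: one root seed deterministically derives per-replicate
#' streams. Replicates whose populations go extinct (possible under lethal
#' fitness states) are resampled up to `max_retries` times and flagged.
#'
#' @param config a [simulation_config()].
#' @param replicates number of strains to simulate.
#' @param seed integer root seed.
#' @param keep_lineage also record the bottleneck clone's karyotype per round.
#' @return list with `karyotypes` (integer matrix, replicates x chromosomes),
#'   `retries` (per-replicate resample counts) and, if requested, `lineages`.
#' @export
simulate_adaptation <- function(config, replicates, seed,
                                keep_lineage = FALSE) {
  stopifnot(inherits(config, "cin_config"), replicates >= 1)
  seeds <- derive_seeds(seed, replicates)
  C <- nrow(config$genome)
  karyotypes <- matrix(NA_integer_, replicates, C,
                       dimnames = list(paste0("strain", seq_len(replicates)),
                                       config$genome$chrom))
  retries <- integer(replicates)
  lineages <- if (keep_lineage) vector("list", replicates)
  for (r in seq_len(replicates)) {
    res <- NULL
    attempt <- 0L
    while (is.null(res) && attempt <= config$max_retries) {
      res <- local_seed(seeds[r] + attempt, run_one_replicate(config))
      attempt <- attempt + 1L
    }
    if (is.null(res))
      stop("replicate ", r, " extinct after ", config$max_retries, " retries")
    karyotypes[r, ] <- res$karyotype
    retries[r] <- attempt - 1L
    if (keep_lineage) lineages[[r]] <- res$lineage
  }
  out <- list(karyotypes = karyotypes, retries = retries)
  if (keep_lineage) out$lineages <- lineages
  out
}

#' Simulate sequencing reads for a karyotype as BED intervals
#'
#' Per chromosome, the read count is Poisson with mean
#' `depth * length * copy / ploidy` (so `depth` is the euploid read density
#' in reads per base pair) and read start positions are uniform. Fixed read
#' length.
#'
#' @param copies integer copy-number vector aligned with the genome's
#'   chromosomes.
#' @param genome a [genome_build()].
#' @param depth euploid read density, reads per bp.
#' @param read_length read length in bp (default 50).
#' @param seed integer seed.
#' @param path optional BED output file.
#' @return data.frame (`chrom`, `start`, `end`), invisibly written to `path`
#'   when given.
#' @export
simulate_read_counts <- function(copies, genome, depth, read_length = 50,
                                 seed = NULL, path = NULL) {
  stopifnot(depth > 0, length(copies) == nrow(genome))
  p <- basal_ploidy(genome)
  reads <- local_seed(seed, {
    counts <- stats::rpois(nrow(genome), depth * genome$length * copies / p)
    starts <- lapply(seq_len(nrow(genome)), function(i)
      floor(stats::runif(counts[i], 0, genome$length[i] - read_length)))
    data.frame(chrom = rep(genome$chrom, counts),
               start = unlist(starts),
               end = unlist(starts) + read_length,
               stringsAsFactors = FALSE)
  })
  if (!is.null(path)) write_bed(reads, path)
  reads
}

#' Write reads as a BED3 file
#' @param reads data.frame with `chrom`, `start`, `end`.
#' @param path output file.
#' @export
write_bed <- function(reads, path) {
  utils::write.table(reads[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a double-disome colony-size matrix
#'
#' `size[a,b] = base * g[a] * g[b] * eps[a,b] * exp(N(0, noise_sigma))`:
#' multiplicative single-disome effects `g`, pairwise interaction terms
#' `eps` (default 1 = no interaction) and lognormal measurement noise. The
#' diagonal (the same chromosome from both marker sets) is not constructible
#' and is left missing.
#'
#' @param g named positive vector of single-disome fitness effects.
#' @param eps symmetric interaction matrix (same names as `g`), or NULL.
#' @param base baseline colony size, mm^2.
#' @param noise_sigma lognormal noise sd (0 = noise-free).
#' @param seed integer seed.
#' @return numeric matrix with NA diagonal.
#' @export
simulate_colony_matrix <- function(g, eps = NULL, base = 100,
                                   noise_sigma = 0, seed = NULL) {
  stopifnot(all(g > 0), base > 0, noise_sigma >= 0)
  C <- length(g)
  if (is.null(eps)) eps <- matrix(1, C, C, dimnames = list(names(g), names(g)))
  stopifnot(all(eps > 0))
  local_seed(seed, {
    M <- base * outer(g, g) * eps *
      exp(matrix(stats::rnorm(C * C, 0, noise_sigma), C, C))
    dimnames(M) <- list(names(g), names(g))
    diag(M) <- NA_real_
    M
  })
}

#' Simulate an arm-level tumor segment table (SEG)
#'
#' Per sample x arm, the arm's true level is `log2((2 + call)/2)` (so calls
#' -1/0/+1 give the standard monosomy/euploid/trisomy log2 ratios); the arm
#' is split into 1-5 abutting segments whose values get independent Gaussian
#' noise. With probability `focal_rate` per sample, one arm additionally
#' receives a short high-amplitude focal segment (amplitude
#' `focal_magnitude`, fraction `focal_fraction` of the arm), the artifact
#' class the mean-median gap filter is designed to catch.
#'
#' @param arm_calls integer matrix (-1/0/+1), samples x arms, with arm names
#'   matching `arms$name`.
#' @param arms data.frame from [build_arm_model()].
#' @param noise_sigma per-segment Gaussian noise sd (log2 units).
#' @param focal_rate probability a sample carries one focal event.
#' @param seed integer seed.
#' @param focal_magnitude log2 amplitude added to the focal segment.
#' @param focal_fraction arm fraction covered by the focal segment.
#' @param path optional SEG output file.
#' @return SEG-style data.frame (`Sample`, `Chromosome`, `Start`, `End`,
#'   `Segment_Mean`; 1-based inclusive coordinates as written by
#'   [write_seg()]).
#' @export
simulate_segment_tables <- function(arm_calls, arms, noise_sigma = 0,
                                    focal_rate = 0, seed = NULL,
                                    focal_magnitude = 2, focal_fraction = 0.05,
                                    path = NULL) {
  stopifnot(all(colnames(arm_calls) %in% arms$name))
  seg <- local_seed(seed, {
    rows <- list()
    for (s in rownames(arm_calls)) {
      focal_arm <- if (stats::runif(1) < focal_rate)
        sample(colnames(arm_calls), 1) else NA_character_
      for (a in colnames(arm_calls)) {
        arm <- arms[arms$name == a, ]
        level <- log2((2 + arm_calls[s, a]) / 2)
        n_pieces <- sample.int(5, 1)
        cuts <- sort(c(arm$start, arm$end,
                       if (n_pieces > 1)
                         floor(stats::runif(n_pieces - 1, arm$start, arm$end))))
        cuts <- unique(cuts)
        for (i in seq_len(length(cuts) - 1)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, chrom = arm$chrom,
            start = cuts[i], end = cuts[i + 1],
            value = level + stats::rnorm(1, 0, noise_sigma),
            stringsAsFactors = FALSE)
        }
        if (!is.na(focal_arm) && focal_arm == a) {
          # replace a slice in the middle of the arm with a focal event
          width <- round((arm$end - arm$start) * focal_fraction)
          fs <- floor((arm$start + arm$end) / 2 - width / 2)
          fe <- fs + width
          n <- length(rows)
          keep <- list()
          for (r in rows[(n - length(cuts) + 2):n]) {
            if (r$end <= fs || r$start >= fe) { keep[[length(keep) + 1]] <- r; next }
            if (r$start < fs) { r1 <- r; r1$end <- fs; keep[[length(keep) + 1]] <- r1 }
            if (r$end > fe) { r2 <- r; r2$start <- fe; keep[[length(keep) + 1]] <- r2 }
          }
          keep[[length(keep) + 1]] <- data.frame(
            sample = s, chrom = arm$chrom, start = fs, end = fe,
            value = level + focal_magnitude, stringsAsFactors = FALSE)
          rows <- c(rows[seq_len(n - length(cuts) + 1)], keep)
        }
      }
    }
    do.call(rbind, rows)
  })
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  if (!is.null(path)) write_seg(seg, path)
  seg
}

#' Write segments as a SEG file (1-based inclusive, tab-separated header)
#' @param seg data.frame with `sample`, `chrom`, `start`, `end`, `value`
#'   (0-based half-open, as used internally).
#' @param path output file.
#' @export
write_seg <- function(seg, path) {
  out <- data.frame(Sample = seg$sample, Chromosome = seg$chrom,
                    Start = seg$start + 1, End = seg$end,
                    Segment_Mean = seg$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
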