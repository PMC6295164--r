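#' Load aligned read positions from a BED file
#'
#' Reads BED3+ (tab-separated, 0-based half-open). When a genome build is
#' supplied, intervals on chromosomes absent from the build are dropped with
#' a warning reporting how many were removed.
#'
#' @param path BED file path.
#' @param genome optional [genome_build()]; unknown chromosomes are dropped.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
load_read_positions <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0) stop("empty BED file: ", path)
  x <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(x) == 0) stop("empty BED file: ", path)
  if (ncol(x) < 3) stop("BED file needs at least 3 tab-separated columns")
  reads <- data.frame(chrom = as.character(x[[1]]),
                      start = suppressWarnings(as.numeric(x[[2]])),
                      end   = suppressWarnings(as.numeric(x[[3]])),
                      stringsAsFactors = FALSE)
  bad <- which(is.na(reads$start) | is.na(reads$end))
  if (length(bad))
    stop("non-numeric coordinates at line ", bad[1], " of ", path)
  bad <- which(reads$start >= reads$end)
  if (length(bad))
    stop("start >= end at line ", bad[1], " of ", path)
  if (!is.null(genome)) {
    unknown <- !(reads$chrom %in% genome$chrom)
    if (any(unknown)) {
      warning(sum(unknown), " read(s) on chromosomes absent from the genome build dropped")
      reads <- reads[!unknown, , drop = FALSE]
      rownames(reads) <- NULL
    }
  }
  reads
}

#' Per-chromosome read densities with telomere exclusion
#'
#' Assigns each read to a chromosome by its midpoint and counts it only when
#' the midpoint falls inside the telomere-trimmed body of the chromosome,
#' `[telomere_exclusion, length - telomere_exclusion)`. Density is the count
#' divided by the usable (trimmed) length, which normalizes for chromosome
#' size. Setting `subtelomeres_only = TRUE` inverts the window and counts
#' only reads whose midpoints fall within the terminal windows.
#'
#' @param reads data.frame from [load_read_positions()].
#' @param genome a [genome_build()].
#' @param subtelomeres_only invert the exclusion window (default FALSE).
#' @return data.frame, one row per genome chromosome, with columns `chrom`,
#'   `usable_length`, `read_count`, `density` (reads per bp).
#' @export
compute_chromosome_densities <- function(reads, genome, subtelomeres_only = FALSE) {
  excl <- telomere_exclusion(genome)
  unknown <- setdiff(unique(reads$chrom), genome$chrom)
  if (length(unknown))
    stop("reads on chromosomes not in the genome build: ",
         paste(unknown, collapse = ", "))
  mid <- (reads$start + reads$end) / 2
  len <- genome$length[match(reads$chrom, genome$chrom)]
  in_body <- mid >= excl & mid < (len - excl)
  keep <- if (subtelomeres_only) !in_body else in_body
  counts <- table(factor(reads$chrom[keep], levels = genome$chrom))
  usable <- if (subtelomeres_only) rep(2 * excl, nrow(genome))
            else genome$length - 2 * excl
  data.frame(chrom = genome$chrom,
             usable_length = usable,
             read_count = as.integer(counts),
             density = as.integer(counts) / usable,
             stringsAsFactors = FALSE)
}

# ascending density ranks with ties broken by chromosome input order;
# the baseline set is rank positions ceil(C/4) < r <= ceil(C/2)
baseline_quartile_index <- function(densities) {
  C <- length(densities)
  r <- order(order(densities, seq_along(densities)))
  which(r > ceiling(C / 4) & r <= ceiling(C / 2))
}

#' Estimate continuous chromosome copy numbers from read densities
#'
#' Chromosomes are ranked by density; the mean density of the second-lowest
#' quartile (rank positions strictly above C/4 and at most C/2, ties broken
#' by chromosome order) is the euploid baseline. Using the second-lowest
#' quartile makes the baseline robust both to chromosome gains (which inflate
#' the top ranks) and to the occasional poorly covered chromosome at the
#' bottom. Copy number is `basal_ploidy * density / baseline`.
#'
#' @param profile data.frame from [compute_chromosome_densities()].
#' @param genome a [genome_build()] (supplies the basal ploidy).
#' @param baseline_stat "mean" (default) or "median" of the baseline
#'   quartile's densities.
#' @return The profile with added columns `copy`, `baseline_density` and
#'   `ploidy`.
#' @export
estimate_copy_numbers <- function(profile, genome,
                                  baseline_stat = c("mean", "median")) {
  baseline_stat <- match.arg(baseline_stat)
  if (nrow(profile) < 4)
    stop("at least 4 chromosomes are needed to define the baseline quartile")
  if (all(profile$density == 0))
    stop("all chromosome densities are zero")
  idx <- baseline_quartile_index(profile$density)
  baseline <- if (baseline_stat == "mean") mean(profile$density[idx])
              else stats::median(profile$density[idx])
  if (baseline <= 0)
    stop("baseline density is zero; coverage too sparse to normalize")
  profile$copy <- basal_ploidy(genome) * profile$density / baseline
  profile$baseline_density <- baseline
  profile$ploidy <- basal_ploidy(genome)
  profile
}

#' Integer aneuploidy calls from continuous copy estimates
#'
#' Rounds each copy estimate to the nearest integer, with exact .5 values
#' rounded away from the basal ploidy (1.5 -> 2 in haploids; 1.5 -> 1 and
#' 2.5 -> 3 in diploids), so borderline values are called aneuploid rather
#' than silently normalized. A call of zero copies (nullisomy, lethal for
#' any chromosome in vivo) is emitted with a warning.
#'
#' @param estimate data.frame from [estimate_copy_numbers()], or a numeric
#'   vector of copy values.
#' @param ploidy basal ploidy; defaults to the `ploidy` column of `estimate`.
#' @return For a data.frame input, the same with added `integer_copy` and
#'   `aneuploid` columns; for a vector, the integer calls.
#' @export
call_aneuploidy <- function(estimate, ploidy = NULL) {
  copies <- if (is.data.frame(estimate)) estimate$copy else as.numeric(estimate)
  if (is.null(ploidy)) {
    if (is.data.frame(estimate) && !is.null(estimate$ploidy))
      ploidy <- estimate$ploidy[1]
    else stop("ploidy must be supplied")
  }
  if (any(!is.finite(copies)) || any(copies < 0))
    stop("copy estimates must be finite and non-negative")
  ic <- round_away_from_ploidy(copies, ploidy)
  if (any(ic == 0))
    warning(sum(ic == 0), " chromosome(s) called nullisomic (copy 0); ",
            "nullisomy is lethal in vivo - check coverage")
  if (is.data.frame(estimate)) {
    estimate$integer_copy <- ic
    estimate$aneuploid <- ic != ploidy
    estimate
  } else ic
}

# round to nearest integer; exact .5 goes away from the basal ploidy
round_away_from_ploidy <- function(copies, ploidy) {
  d <- copies - ploidy
  ic <- ploidy + sign(d) * floor(abs(d) + 0.5)
  as.integer(pmax(ic, 0))
}

#' Call a strain's whole-chromosome karyotype from a BED file
#'
#' Convenience wrapper running [load_read_positions()],
#' [compute_chromosome_densities()], [estimate_copy_numbers()] and
#' [call_aneuploidy()] in sequence.
#'
#' @param bed BED file path, or a read data.frame as returned by
#'   [load_read_positions()].
#' @param genome a [genome_build()].
#' @inheritParams estimate_copy_numbers
#' @inheritParams compute_chromosome_densities
#' @return Per-chromosome karyotype table with columns `chrom`, `read_count`,
#'   `usable_length`, `density`, `copy`, `integer_copy`, `aneuploid`.
#' @export
call_karyotype <- function(bed, genome, baseline_stat = "mean",
                           subtelomeres_only = FALSE) {
  reads <- if (is.character(bed)) load_read_positions(bed, genome) else bed
  prof <- compute_chromosome_densities(reads, genome, subtelomeres_only)
  est <- estimate_copy_numbers(prof, genome, baseline_stat)
  out <- call_aneuploidy(est)
  out[, c("chrom", "read_count", "usable_length", "density",
          "copy", "integer_copy", "aneuploid")]
}

#' Write a per-strain karyotype table as TSV
#' @param karyotype data.frame from [call_karyotype()].
#' @param path output file.
#' @export
write_karyotype_tsv <- function(karyotype, path) {
  utils::write.table(karyotype, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a strains x chromosomes copy-number matrix from TSV
#'
#' Rows are strains, columns chromosomes, values continuous copy numbers.
#' @param path TSV with a header row of chromosome names and strain ids in
#'   the first column.
#' @return numeric matrix with strain rownames and chromosome colnames.
#' @export
read_karyotype_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(x)
}

#' Write a strains x chromosomes copy-number matrix as TSV
#' @param mat numeric matrix, strains in rows.
#' @param path output file.
#' @export
write_karyotype_matrix <- function(mat, path) {
  utils::write.table(data.frame(strain = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
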