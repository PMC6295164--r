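#' Define a genome build
#'
#' A genome build is the fixed reference the karyotype caller works against:
#' an ordered set of chromosomes with lengths, the strain's basal ploidy, and
#' the width of the telomere-proximal window excluded from read counting.
#' Subtelomeric repeats map poorly and bias read densities, so by default the
#' terminal `telomere_exclusion` base pairs of each chromosome end are dropped
#' before densities are computed.
#'
#' @param chromosomes character vector of unique chromosome names, in order.
#' @param lengths integer vector of chromosome lengths in base pairs.
#' @param basal_ploidy basal chromosome set count (1 haploid, 2 diploid).
#' @param telomere_exclusion base pairs excluded from each chromosome end
#'   (default 15000).
#' @return A `genome_build` object: a data.frame with columns `chrom`,
#'   `length` and `fraction` (the genome fraction f_i = length_i / sum of
#'   lengths), with `basal_ploidy` and `telomere_exclusion` attributes.
#' @export
genome_build <- function(chromosomes, lengths, basal_ploidy = 1L,
                         telomere_exclusion = 15000) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have the same length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (basal_ploidy < 1 || basal_ploidy != round(basal_ploidy))
    stop("basal_ploidy must be a positive integer")
  if (telomere_exclusion < 0)
    stop("telomere_exclusion must be non-negative")
  bad <- lengths <= 2 * telomere_exclusion
  if (any(bad))
    stop("chromosome(s) shorter than twice the telomere exclusion: ",
         paste(chromosomes[bad], collapse = ", "))
  g <- data.frame(chrom = chromosomes, length = lengths,
                  fraction = lengths / sum(lengths),
                  stringsAsFactors = FALSE)
  attr(g, "basal_ploidy") <- as.integer(basal_ploidy)
  attr(g, "telomere_exclusion") <- telomere_exclusion
  class(g) <- c("genome_build", "data.frame")
  g
}

#' Read a genome definition from a two-column TSV (name, length)
#'
#' @param path TSV file with columns chromosome name and length; a header is
#'   detected and skipped if the second field is non-numeric.
#' @inheritParams genome_build
#' @return A [genome_build()] object.
#' @export
read_genome_tsv <- function(path, basal_ploidy = 1L, telomere_exclusion = 15000) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(x) < 2) stop("genome TSV needs two columns: name, length")
  if (is.na(suppressWarnings(as.numeric(x[1, 2])))) x <- x[-1, , drop = FALSE]
  genome_build(x[[1]], as.numeric(x[[2]]), basal_ploidy, telomere_exclusion)
}

basal_ploidy <- function(genome) attr(genome, "basal_ploidy")
telomere_exclusion <- function(genome) attr(genome, "telomere_exclusion")

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome_build: %d chromosomes, %.3g bp, ploidy %d, telomere exclusion %g bp\n",
              nrow(x), sum(x$length), basal_ploidy(x), telomere_exclusion(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' The 16 Saccharomyces cerevisiae chromosomes (sacCer3 lengths)
#'
#' Convenience constructor for the standard yeast nuclear genome. `scale`
#' shrinks lengths (and the telomere exclusion) proportionally, which is
#' useful for fast simulation studies at reduced read counts.
#'
#' @param basal_ploidy 1 or 2.
#' @param scale multiplicative factor applied to lengths and exclusion.
#' @return A [genome_build()].
#' @export
yeast_genome <- function(basal_ploidy = 1L, scale = 1) {
  lens <- c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
            chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
            chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
            chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)
  genome_build(names(lens), round(lens * scale), basal_ploidy,
               telomere_exclusion = 15000 * scale)
}
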