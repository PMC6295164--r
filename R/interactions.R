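#' Normalize a double-disome colony-size matrix to relative fitness
#'
#' Colony sizes of engineered double-disomic strains confound each
#' chromosome's single-disome fitness cost (and marker-set effects) with the
#' pairwise interaction of interest. Row and column effects are removed
#' multiplicatively: `rel[a,b] = M[a,b] * G / (R_a * C_b)` with `R_a` the
#' mean of present cells in row a, `C_b` the column mean and `G` the grand
#' mean. On an interaction-free (rank-1) matrix `M[a,b] = r_a * c_b` this is
#' exactly 1 everywhere, so deviations from 1 isolate the pairwise term.
#' Missing cells (the diagonal, unscored combinations) stay missing and are
#' excluded from all means. `stat = "median"` swaps medians in for means.
#'
#' @param M numeric matrix of mean colony sizes (mm^2), disomy A in rows,
#'   disomy B in columns; NA for missing cells.
#' @param stat "mean" (default) or "median" row/column summaries.
#' @return matrix of the same shape with dimensionless relative fitness
#'   values.
#' @export
normalize_colony_matrix <- function(M, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!is.matrix(M)) M <- as.matrix(M)
  if (any(M <= 0, na.rm = TRUE)) stop("colony sizes must be positive")
  npres_row <- rowSums(!is.na(M))
  npres_col <- colSums(!is.na(M))
  if (any(npres_row < 2))
    stop("row(s) with fewer than 2 present cells: ",
         paste(rownames(M)[npres_row < 2] %||% which(npres_row < 2), collapse = ", "))
  if (any(npres_col < 2))
    stop("column(s) with fewer than 2 present cells: ",
         paste(colnames(M)[npres_col < 2] %||% which(npres_col < 2), collapse = ", "))
  f <- if (stat == "mean") mean else stats::median
  R <- apply(M, 1, f, na.rm = TRUE)
  C <- apply(M, 2, f, na.rm = TRUE)
  G <- f(M[!is.na(M)])
  M * G / outer(R, C)
}

#' Chromosome copy-number interaction (CCNI) scores
#'
#' Each unordered chromosome pair was scored in two marker orientations
#' (disomy A from marker set 1 with disomy B from set 2, and vice versa); the
#' CCNI score is the mean of the two relative-fitness values, or the single
#' value when only one orientation was scored (flagged). Scores below 1
#' indicate a negative interaction (the double disome grows worse than its
#' single-disome effects predict); above 1, a positive one.
#'
#' @param rel matrix from [normalize_colony_matrix()]; row and column names
#'   identify the chromosomes.
#' @return data.frame with `chrom_a`, `chrom_b` (unordered pair), `score`,
#'   `value_ab`, `value_ba` and `single_orientation`.
#' @export
ccni_scores <- function(rel) {
  if (!is.matrix(rel)) rel <- as.matrix(rel)
  chroms <- union(rownames(rel) %||% seq_len(nrow(rel)),
                  colnames(rel) %||% seq_len(ncol(rel)))
  pairs <- utils::combn(length(chroms), 2)
  pick <- function(a, b) {
    if (a %in% rownames(rel) && b %in% colnames(rel)) rel[a, b] else NA_real_
  }
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- chroms[pairs[1, j]]; b <- chroms[pairs[2, j]]
    ab <- pick(a, b); ba <- pick(b, a)
    vals <- c(ab, ba)
    if (all(is.na(vals))) return(NULL)
    data.frame(chrom_a = a, chrom_b = b,
               score = mean(vals, na.rm = TRUE),
               value_ab = ab, value_ba = ba,
               single_orientation = sum(!is.na(vals)) == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlate CCNI scores with cohort copy-number correlations
#'
#' Tests whether pairwise fitness interactions measured in engineered double
#' disomes predict which aneuploidies co-occur in an adapted cohort: Pearson
#' correlation between the CCNI score and the cohort copy-number correlation
#' coefficient over the chromosome pairs present in both, with a two-tailed
#' p-value from the t distribution on (pairs - 2) degrees of freedom.
#'
#' @param scores data.frame from [ccni_scores()].
#' @param corr_pairs data.frame with `chrom_a`, `chrom_b`, `r` (e.g. the
#'   `pairs` element of [copy_correlation_matrix()]).
#' @return list with `r`, `p` (two-tailed), `n_pairs` and the merged table.
#' @export
correlate_ccni_with_cooccurrence <- function(scores, corr_pairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  s <- scores[!is.na(scores$score), , drop = FALSE]
  cp <- corr_pairs[!is.na(corr_pairs$r), , drop = FALSE]
  m <- merge(data.frame(pair = key(s$chrom_a, s$chrom_b), score = s$score),
             data.frame(pair = key(cp$chrom_a, cp$chrom_b), r = cp$r),
             by = "pair")
  if (nrow(m) < 3) stop("need at least 3 shared chromosome pairs")
  ct <- stats::cor.test(m$score, m$r, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(m), pairs = m)
}

#' Read a colony-size matrix TSV (row/column chromosome labels, blanks = NA)
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_colony_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE, na.strings = c("", "NA"))
  as.matrix(x)
}

#' Write a colony-size or relative-fitness matrix as TSV
#' @param M numeric matrix.
#' @param path output file.
#' @export
write_colony_matrix <- function(M, path) {
  utils::write.table(data.frame(chrom = rownames(M), M, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
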