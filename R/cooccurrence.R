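#' Hypergeometric point probability of an observed overlap
#'
#' The co-occurrence statistic: in a cohort of `N` strains where `K` carry
#' event A and `n` carry event B, the probability of observing exactly `k`
#' strains with both, if the two events were assigned independently:
#' \deqn{P(X = k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}.}
#' A small value means the observed overlap is unlikely under independence;
#' whether it signals enrichment (co-occurrence) or exclusivity is decided
#' by the sign of `k - nK/N`. Computed in log space so extreme probabilities
#' (down to ~1e-300) stay exact. Vectorized over all arguments.
#'
#' @param N cohort size.
#' @param K strains with event A.
#' @param n strains with event B.
#' @param k strains with both.
#' @return probability in (0, 1].
#' @seealso [hypergeometric_tail()] for the cumulative variant.
#' @export
hypergeometric_point <- function(N, K, n, k) {
  m <- cbind(N, K, n, k)
  N <- m[, 1]; K <- m[, 2]; n <- m[, 3]; k <- m[, 4]
  if (any(c(N, K, n, k) != floor(c(N, K, n, k))))
    stop("N, K, n, k must be integers")
  if (any(K > N | n > N | K < 0 | n < 0 | N < 0))
    stop("need 0 <= K <= N and 0 <= n <= N")
  if (any(k > pmin(K, n) | k < pmax(0, K + n - N)))
    stop("k outside the hypergeometric support [max(0, K+n-N), min(K, n)]")
  unname(exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)))
}

#' Cumulative hypergeometric tail probability
#'
#' Lower tail (P(X <= k), exclusivity) or upper tail (P(X >= k),
#' enrichment), as an alternative to the point statistic.
#'
#' @inheritParams hypergeometric_point
#' @param direction "exclusivity" for the lower tail, "enrichment" for the
#'   upper.
#' @return tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k,
                                direction = c("exclusivity", "enrichment")) {
  direction <- match.arg(direction)
  hypergeometric_point(N, K, n, k)  # reuse the domain checks
  if (direction == "exclusivity")
    stats::phyper(k, K, N - K, n)
  else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-chromosome aneuploidy frequencies in a cohort
#'
#' @param calls integer matrix of copy-number calls, strains in rows,
#'   chromosomes in columns.
#' @param ploidy basal ploidy of the cohort.
#' @return data.frame with per-chromosome `frequency` (any deviation from the
#'   basal ploidy), and `gain_frequency` / `loss_frequency` separately.
#' @export
aneuploidy_frequency <- function(calls, ploidy) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  if (nrow(calls) < 1) stop("need at least one strain")
  data.frame(chrom = colnames(calls) %||% paste0("chr", seq_len(ncol(calls))),
             frequency = colMeans(calls != ploidy),
             gain_frequency = colMeans(calls > ploidy),
             loss_frequency = colMeans(calls < ploidy),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent change in DNA content of a karyotype
#'
#' The aneuploidy burden of a karyotype as a percentage of the euploid genome:
#' each chromosome's copy deviation from the basal ploidy is weighted by the
#' fraction of the genome that chromosome represents, summed in absolute
#' value, and normalized to the ploidy:
#' \deqn{100 \sum_i |c_i - p|\, f_i / p.}
#' For haploid cohorts with gains only this equals the signed sum of
#' (copy - 1) weighted by genome fraction.
#'
#' @param calls integer copy vector (one strain) or matrix (strains x
#'   chromosomes) aligned with the genome's chromosomes.
#' @param genome a [genome_build()].
#' @return percentage (scalar for a vector input, per-strain vector for a
#'   matrix).
#' @export
dna_content_change <- function(calls, genome) {
  p <- basal_ploidy(genome)
  f <- genome$fraction
  if (is.matrix(calls)) {
    if (ncol(calls) != nrow(genome))
      stop("calls and genome must cover the same chromosomes")
    100 * as.numeric(abs(sweep(calls, 2, p)) %*% f) / p
  } else {
    if (length(calls) != nrow(genome))
      stop("calls and genome must cover the same chromosomes")
    100 * sum(abs(calls - p) * f) / p
  }
}

#' Pooled standard deviation of a karyotype cohort
#'
#' Homogeneity measure: the square root of the mean per-chromosome sample
#' variance of copy numbers across strains. Decreases as a cohort converges
#' on a common karyotype.
#'
#' @param mat numeric matrix of continuous copy numbers, strains in rows.
#' @return non-negative scalar.
#' @export
karyotype_pooled_sd <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least two strains")
  sqrt(mean(apply(mat, 2, stats::var)))
}

#' Binary event matrix from integer calls
#'
#' Expands integer copy calls into direction-specific aneuploidy events.
#' Haploid cohorts use gain events only by default (losses are lethal);
#' diploid cohorts get distinct gain and loss events per chromosome.
#'
#' @param calls integer call matrix, strains x chromosomes.
#' @param ploidy basal ploidy.
#' @param include_losses include loss events (default: ploidy >= 2).
#' @return logical matrix, strains x events, event names `<chrom>:gain` /
#'   `<chrom>:loss`; events observed in zero strains are dropped.
#' @export
aneuploidy_events <- function(calls, ploidy, include_losses = ploidy >= 2) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  chroms <- colnames(calls) %||% paste0("chr", seq_len(ncol(calls)))
  gains <- calls > ploidy
  colnames(gains) <- paste0(chroms, ":gain")
  ev <- gains
  if (include_losses) {
    losses <- calls < ploidy
    colnames(losses) <- paste0(chroms, ":loss")
    ev <- cbind(gains, losses)
  }
  ev[, colSums(ev) > 0, drop = FALSE]
}

#' Pairwise co-occurrence / exclusivity tests over aneuploidy events
#'
#' For every unordered pair of observed aneuploidy events, builds the
#' contingency counts (N strains, K with event A, n with event B, k with
#' both) and computes the hypergeometric probability. `direction` is
#' "enrichment" when the observed overlap exceeds the independence
#' expectation nK/N, "exclusivity" when below it.
#'
#' @param calls integer call matrix, strains x chromosomes.
#' @param ploidy basal ploidy.
#' @param stat "point" (default; probability of exactly the observed overlap)
#'   or "tail" (cumulative in the observed direction).
#' @inheritParams aneuploidy_events
#' @return data.frame with one row per event pair: `event_a`, `event_b`, `N`,
#'   `K`, `n`, `k`, `expected`, `direction`, `p`.
#' @export
pairwise_cooccurrence <- function(calls, ploidy, stat = c("point", "tail"),
                                  include_losses = ploidy >= 2) {
  stat <- match.arg(stat)
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  if (nrow(calls) < 2) stop("need at least two strains")
  ev <- aneuploidy_events(calls, ploidy, include_losses)
  if (ncol(ev) < 2) stop("need at least two events with nonzero frequency")
  N <- nrow(ev)
  pairs <- utils::combn(ncol(ev), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    K <- sum(ev[, a]); n <- sum(ev[, b]); k <- sum(ev[, a] & ev[, b])
    expected <- n * K / N
    direction <- if (k >= expected) "enrichment" else "exclusivity"
    p <- if (stat == "point") hypergeometric_point(N, K, n, k)
         else hypergeometric_tail(N, K, n, k, direction)
    data.frame(event_a = colnames(ev)[a], event_b = colnames(ev)[b],
               N = N, K = K, n = n, k = k, expected = expected,
               direction = direction, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations between chromosome copy numbers
#'
#' Correlates continuous copy estimates across strains for every chromosome
#' pair. Pairs are marked not-included when either chromosome shows no
#' aneuploidy in the cohort (no integer call away from the basal ploidy) or
#' has constant copy values (correlation undefined).
#'
#' @param mat numeric matrix of continuous copy numbers, strains x
#'   chromosomes.
#' @param ploidy basal ploidy (used to decide where aneuploidy was observed).
#' @return list with `pairs` (data.frame: `chrom_a`, `chrom_b`, `r`,
#'   `included`) and `matrix` (symmetric correlation matrix, NA where not
#'   included).
#' @export
copy_correlation_matrix <- function(mat, ploidy) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least three strains")
  chroms <- colnames(mat) %||% paste0("chr", seq_len(ncol(mat)))
  calls <- apply(mat, 2, round_away_from_ploidy, ploidy = ploidy)
  observed <- colSums(calls != ploidy) > 0
  constant <- apply(mat, 2, function(x) stats::var(x) == 0)
  ok <- observed & !constant
  cm <- matrix(NA_real_, ncol(mat), ncol(mat), dimnames = list(chroms, chroms))
  if (any(ok)) {
    sub <- stats::cor(mat[, ok, drop = FALSE])
    cm[ok, ok] <- sub
  }
  diag(cm) <- NA_real_
  pairs <- utils::combn(ncol(mat), 2)
  df <- data.frame(chrom_a = chroms[pairs[1, ]], chrom_b = chroms[pairs[2, ]],
                   r = cm[t(pairs)],
                   included = ok[pairs[1, ]] & ok[pairs[2, ]],
                   row.names = NULL, stringsAsFactors = FALSE)
  df$r[!df$included] <- NA_real_
  list(pairs = df, matrix = cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
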