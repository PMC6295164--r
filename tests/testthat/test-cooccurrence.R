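test_that("hypergeometric point probability matches closed forms and dhyper", {
  # empty success class: only one way to draw
  expect_equal(hypergeometric_point(10, 0, 5, 0), 1)
  # exclusivity case with a closed form: C(9,7)/C(25,7) = 36/480700
  expect_equal(hypergeometric_point(25, 16, 7, 0), 36 / 480700)
  # independent check against R's hypergeometric density on a grid
  for (N in c(11, 37, 102)) {
    K <- floor(N / 3); n <- floor(N / 2)
    k <- max(0, K + n - N):min(K, n)
    expect_equal(hypergeometric_point(N, K, n, k), dhyper(k, K, N - K, n),
                 tolerance = 1e-13)
  }
})

test_that("hypergeometric point is symmetric in K and n and sums to 1", {
  expect_equal(hypergeometric_point(40, 12, 20, 7),
               hypergeometric_point(40, 20, 12, 7))
  for (N in c(8, 57, 200)) {
    K <- ceiling(N / 4); n <- ceiling(N / 3)
    k <- max(0, K + n - N):min(K, n)
    expect_equal(sum(hypergeometric_point(N, K, n, k)), 1, tolerance = 1e-12)
  }
})

test_that("hypergeometric arguments outside the support are rejected", {
  expect_error(hypergeometric_point(10, 4, 4, 5), "support")
  expect_error(hypergeometric_point(10, 4, 8, 1), "support")  # k < K+n-N
  expect_error(hypergeometric_point(10, 11, 4, 2), "K <= N")
})

test_that("hypergeometric tail statistic matches phyper in both directions", {
  expect_equal(hypergeometric_tail(50, 20, 10, 2, "exclusivity"),
               phyper(2, 20, 30, 10))
  expect_equal(hypergeometric_tail(50, 20, 10, 7, "enrichment"),
               phyper(6, 20, 30, 10, lower.tail = FALSE))
})

test_that("aneuploidy frequencies count gains and losses per chromosome", {
  calls <- rbind(c(2L, 1L), c(1L, 1L), c(1L, 1L), c(2L, 1L))
  colnames(calls) <- c("chrA", "chrB")
  f <- aneuploidy_frequency(calls, ploidy = 1)
  expect_equal(f$frequency, c(0.5, 0))
  expect_equal(f$gain_frequency, c(0.5, 0))

  dip <- rbind(c(3L, 2L), c(1L, 2L), c(2L, 2L), c(2L, 2L))
  f2 <- aneuploidy_frequency(dip, ploidy = 2)
  expect_equal(f2$frequency[1], 0.5)
  expect_equal(f2$gain_frequency[1], 0.25)
  expect_equal(f2$loss_frequency[1], 0.25)
})

test_that("planted gain rates are recovered within the binomial 99% CI", {
  g <- toy_genome(16)
  rate <- 0.6; n_strains <- 200
  set.seed(5)
  calls <- matrix(1L, n_strains, 16, dimnames = list(NULL, g$chrom))
  calls[, 7] <- 1L + rbinom(n_strains, 1, rate)
  f <- aneuploidy_frequency(calls, 1)
  ci <- qnorm(0.995) * sqrt(rate * (1 - rate) / n_strains)
  expect_lt(abs(f$frequency[7] - rate), ci)
})

test_that("DNA-content change follows the genome-fraction-weighted formula", {
  g <- genome_build(paste0("c", 1:5), c(4, 24, 24, 24, 24) * 1e4, 1, 1000)
  expect_equal(g$fraction[1], 0.04)
  expect_equal(dna_content_change(rep(1L, 5), g), 0)
  expect_equal(dna_content_change(c(2L, 1L, 1L, 1L, 1L), g), 4)

  g2 <- genome_build(paste0("c", 1:5), c(4, 2, 24, 35, 35) * 1e4, 2, 1000)
  expect_equal(dna_content_change(c(3L, 1L, 2L, 2L, 2L), g2), 3)

  # order invariance and additivity over disjoint aberration sets
  p <- c(2L, 1L, 2L, 1L, 1L)
  perm <- c(3, 1, 5, 2, 4)
  gp <- genome_build(g$chrom[perm], g$length[perm], 1, 1000)
  expect_equal(dna_content_change(p[perm], gp), dna_content_change(p, g))
  a <- c(2L, 1L, 1L, 1L, 1L); b <- c(1L, 1L, 2L, 1L, 1L)
  both <- c(2L, 1L, 2L, 1L, 1L)
  expect_equal(dna_content_change(both, g),
               dna_content_change(a, g) + dna_content_change(b, g))
})

test_that("pooled karyotype SD matches hand arithmetic and scales linearly", {
  mat <- matrix(1, 2, 16)
  expect_equal(karyotype_pooled_sd(mat), 0)
  mat[, 4] <- c(1, 2)  # sample variance 0.5 on one chromosome
  expect_equal(karyotype_pooled_sd(mat), sqrt(0.5 / 16))

  set.seed(9)
  m2 <- matrix(rnorm(80, 1, 0.2), 5, 16)
  alpha <- 3
  m3 <- sweep(m2, 2, colMeans(m2))  # center, then scale spread
  expect_equal(karyotype_pooled_sd(sweep(alpha * m3, 2, colMeans(m2), "+")),
               alpha * karyotype_pooled_sd(m2), tolerance = 1e-12)
})

test_that("pairwise co-occurrence builds the right contingency counts", {
  # two events in disjoint strain sets of sizes 16 and 7 in a 25-strain cohort
  calls <- matrix(2L, 25, 3, dimnames = list(NULL, c("c13", "c9", "c1")))
  calls[1:16, 1] <- 3L  # trisomy 13
  calls[17:23, 2] <- 1L  # monosomy 9
  calls[1:2, 3] <- 3L  # a third event so more pairs exist
  res <- pairwise_cooccurrence(calls, ploidy = 2)
  row <- res[res$event_a == "c13:gain" & res$event_b == "c9:loss", ]
  expect_equal(row$N, 25); expect_equal(row$K, 16)
  expect_equal(row$n, 7); expect_equal(row$k, 0)
  expect_equal(row$direction, "exclusivity")
  expect_equal(row$p, 36 / 480700)

  # identical strain sets give perfect co-occurrence
  calls2 <- matrix(1L, 10, 2, dimnames = list(NULL, c("a", "b")))
  calls2[1:4, ] <- 2L
  res2 <- pairwise_cooccurrence(calls2, ploidy = 1)
  expect_equal(res2$k, res2$K)
  expect_equal(res2$direction, "enrichment")
  expect_equal(res2$p, hypergeometric_point(10, 4, 4, 4))
})

test_that("haploid cohorts use gain-only events by default", {
  calls <- matrix(1L, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  calls[1:3, 1] <- 2L
  calls[4:6, 2] <- 0L
  calls[1:3, 3] <- 2L
  ev <- aneuploidy_events(calls, ploidy = 1)
  expect_equal(colnames(ev), c("a:gain", "c:gain"))
  ev2 <- aneuploidy_events(calls, ploidy = 1, include_losses = TRUE)
  expect_true("b:loss" %in% colnames(ev2))
})

test_that("copy correlations flag undefined and unobserved pairs", {
  a <- c(1.2, 1.8, 1.4, 1.6, 1.3, 1.7, 1.25, 1.75, 1.45, 1.55)
  mat <- cbind(a = a, b = a, c = 2 - a, d = rep(1, 10))
  cc <- copy_correlation_matrix(mat, ploidy = 1)
  pr <- cc$pairs
  get <- function(x, y) pr[pr$chrom_a == x & pr$chrom_b == y, ]
  expect_equal(get("a", "b")$r, 1)
  expect_equal(get("a", "c")$r, -1, tolerance = 1e-12)
  expect_false(get("a", "d")$included)  # constant column
  expect_true(is.na(get("a", "d")$r))
  expect_true(all(is.na(diag(cc$matrix))))
  expect_equal(cc$matrix["a", "b"], cc$matrix["b", "a"])
})

test_that("null co-occurrence p-values fire near the point statistic's null rate", {
  # independent events: the point probability of the observed overlap is
  # rarely small; compare the empirical rate with the exact null rate
  # computed by enumeration over the overlap distribution
  set.seed(21)
  n_strains <- 1000; reps <- 200; alpha <- 0.05
  fire <- logical(reps)
  exact_rate <- numeric(reps)
  for (r in seq_len(reps)) {
    a <- rbinom(n_strains, 1, 0.3) == 1
    b <- rbinom(n_strains, 1, 0.3) == 1
    K <- sum(a); n <- sum(b); k <- sum(a & b)
    p <- hypergeometric_point(n_strains, K, n, k)
    fire[r] <- p < alpha
    supp <- max(0, K + n - n_strains):min(K, n)
    pmf <- hypergeometric_point(n_strains, K, n, supp)
    exact_rate[r] <- sum(pmf[pmf < alpha])
  }
  expect_lt(abs(mean(fire) - mean(exact_rate)), 0.05)
})
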