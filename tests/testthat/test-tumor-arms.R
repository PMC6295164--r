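seg_lines <- function(rows) {
  c("Sample\tChromosome\tStart\tEnd\tSegment_Mean", rows)
}

test_that("SEG loading normalizes names and coordinates and checks overlaps", {
  path <- tmpfile_with(seg_lines("S1\tchr1\t1\t1000\t0.5"), ".seg")
  seg <- load_segments(path)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$value, 0.5)
  expect_equal(seg$start, 0)  # 1-based inclusive -> 0-based half-open
  expect_equal(seg$end, 1000)

  # "1" and "chr1" map to the same chromosome key
  p2 <- tmpfile_with(seg_lines(c("S1\tchr1\t1\t1000\t0.5",
                                 "S2\t1\t1\t1000\t0.3")), ".seg")
  expect_equal(unique(load_segments(p2)$chrom), "1")

  p3 <- tmpfile_with(seg_lines(c("S1\t1\t1\t1000\t0.5",
                                 "S1\t1\t500\t1500\t0.3")), ".seg")
  expect_error(load_segments(p3), "overlap")

  p4 <- tmpfile_with(c("Sample\tChromosome\tStart\tEnd",
                       "S1\t1\t1\t1000"), ".seg")
  expect_error(load_segments(p4), "Segment_Mean")
})

test_that("arm models come from cytobands with centromeres excluded", {
  bands <- data.frame(chrom = "chr7",
                      start = c(0, 40, 60), end = c(40, 60, 100),
                      band = c("p11", "cen11", "q11"),
                      stain = c("gpos", "acen", "gneg"))
  arms <- build_arm_model(bands)
  expect_equal(arms$name, c("7p", "7q"))
  expect_equal(arms$start, c(0, 60))
  expect_equal(arms$end, c(40, 100))

  # acrocentric: only q bands -> p-arm absent, q-arm built
  acro <- data.frame(chrom = "21", start = c(0, 10), end = c(10, 100),
                     band = c("cen", "q11"), stain = c("acen", "gneg"))
  arms2 <- build_arm_model(acro)
  expect_equal(arms2$name, "21q")

  # order independence
  shuf <- bands[c(3, 1, 2), ]
  expect_equal(build_arm_model(shuf), arms)

  noq <- data.frame(chrom = "9", start = 0, end = 50, band = "p11",
                    stain = "gneg")
  expect_error(build_arm_model(noq), "no q bands")
})

test_that("arm summaries use length-weighted means and medians", {
  arms <- data.frame(chrom = "1", arm = "q", start = 0, end = 1000,
                     name = "1q")
  full <- data.frame(sample = "S1", chrom = "1", start = 0, end = 1000,
                     value = 0.5)
  pr <- summarize_arms(full, arms)
  expect_equal(pr$weighted_mean, 0.5)
  expect_equal(pr$weighted_median, 0.5)
  expect_equal(pr$gap, 0)
  expect_equal(pr$covered_fraction, 1)

  # 60% at 0 and 40% at 0.8: mean 0.32, median 0 -> gap 0.32
  mixed <- data.frame(sample = "S1", chrom = "1",
                      start = c(0, 600), end = c(600, 1000),
                      value = c(0, 0.8))
  pr2 <- summarize_arms(mixed, arms)
  expect_equal(pr2$weighted_mean, 0.32)
  expect_equal(pr2$weighted_median, 0)
  expect_equal(pr2$gap, 0.32)

  # exact 50% boundary takes the lower value
  half <- data.frame(sample = "S1", chrom = "1",
                     start = c(0, 500), end = c(500, 1000),
                     value = c(0.1, 0.3))
  pr3 <- summarize_arms(half, arms)
  expect_equal(pr3$weighted_mean, 0.2)
  expect_equal(pr3$weighted_median, 0.1)
  expect_equal(pr3$gap, 0.1, tolerance = 1e-12)

  # uncovered arm is marked missing
  arms2 <- rbind(arms, data.frame(chrom = "2", arm = "q", start = 0,
                                  end = 1000, name = "2q"))
  pr4 <- summarize_arms(full, arms2)
  expect_true(pr4$missing[pr4$arm == "2q"])
})

test_that("arm summaries are invariant to segment refinement", {
  arms <- data.frame(chrom = "1", arm = "q", start = 0, end = 1000,
                     name = "1q")
  seg <- data.frame(sample = "S1", chrom = "1",
                    start = c(0, 400), end = c(400, 1000),
                    value = c(0.3, -0.1))
  split_seg <- data.frame(sample = "S1", chrom = "1",
                          start = c(0, 150, 400, 700),
                          end = c(150, 400, 700, 1000),
                          value = c(0.3, 0.3, -0.1, -0.1))
  expect_equal(summarize_arms(seg, arms)[, -1],
               summarize_arms(split_seg, arms)[, -1])
})

test_that("arm summaries match a per-base-pair brute-force oracle", {
  arms <- data.frame(chrom = "1", arm = "p", start = 100, end = 5100,
                     name = "1p")
  set.seed(13)
  cuts <- sort(sample(200:5000, 4))
  bounds <- c(0, cuts, 6000)
  seg <- data.frame(sample = "S1", chrom = "1",
                    start = bounds[-length(bounds)], end = bounds[-1],
                    value = round(rnorm(length(bounds) - 1, 0, 0.5), 3))
  pr <- summarize_arms(seg, arms)
  # expand to one value per base pair inside the arm
  bp_vals <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    s <- max(seg$start[i], 100); e <- min(seg$end[i], 5100)
    if (e > s) rep(seg$value[i], e - s) else numeric()
  }))
  expect_equal(pr$weighted_mean, mean(bp_vals))
  srt <- sort(bp_vals)
  expect_equal(pr$weighted_median, srt[ceiling(length(srt) / 2)])
})

test_that("gap filter excludes samples with large focal events (strictly)", {
  arms <- data.frame(chrom = "1", arm = "q", start = 0, end = 1000,
                     name = "1q")
  seg <- rbind(
    data.frame(sample = "clean", chrom = "1", start = 0, end = 1000,
               value = 0.5),
    data.frame(sample = "focal", chrom = "1", start = c(0, 600),
               end = c(600, 1000), value = c(0, 0.8)),      # gap 0.32
    data.frame(sample = "edge", chrom = "1", start = c(0, 500),
               end = c(500, 1000), value = c(0.1, 0.5)))    # gap exactly 0.2
  pr <- summarize_arms(seg, arms)
  flt <- filter_samples(pr, gap_threshold = 0.2)
  expect_setequal(flt$retained, c("clean", "edge"))
  expect_equal(flt$excluded$sample, "focal")
  expect_equal(flt$excluded$gap, 0.32)
})

test_that("aberration calls use an inclusive +/- threshold", {
  pr <- data.frame(sample = "S1", arm = c("1p", "1q", "2p", "2q", "3p"),
                   weighted_mean = c(0.25, -0.05, -0.2, 0.19, NA),
                   weighted_median = 0, gap = 0, covered_fraction = 1,
                   missing = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  calls <- call_arm_aberrations(pr, call_threshold = 0.2)
  expect_equal(unname(calls["S1", ]), c(1L, 0L, -1L, 0L, NA))
})

test_that("complex-karyotype and display filters apply strict counting rules", {
  calls <- rbind(two = c(1L, 0L, -1L), one = c(1L, 0L, 0L),
                 zero = c(0L, 0L, 0L))
  colnames(calls) <- c("1p", "1q", "2p")
  expect_equal(filter_complex(calls), "two")

  big <- matrix(0L, 200, 2, dimnames = list(paste0("s", 1:200),
                                            c("7p", "10q")))
  big[1:25, 1] <- 1L   # 12.5% > 10%
  big[1:20, 2] <- -1L  # exactly 10%, not > 10%
  expect_equal(frequent_arms(big, 0.10), "7p")
})

test_that("synthetic SEG cohorts flag planted exclusive arm classes end to end", {
  arms <- build_arm_model(toy_cytobands(c("1", "7", "10", "19")))
  arm_names <- arms$name
  n <- 60
  calls <- matrix(0L, n, length(arm_names),
                  dimnames = list(sprintf("T%02d", 1:n), arm_names))
  # two mutually exclusive karyotype classes: +7/-10 vs -1p/-19q
  classA <- 1:30; classB <- 31:60
  calls[classA, c("7p", "7q")] <- 1L
  calls[classA, c("10p", "10q")] <- -1L
  calls[classB, "1p"] <- -1L
  calls[classB, "19q"] <- -1L
  seg <- simulate_segment_tables(calls, arms, noise_sigma = 0.02, seed = 17)
  res <- tumor_arm_analysis(load_segments(write_seg(seg, tempfile())),
                            arms)
  expect_setequal(rownames(res$calls), rownames(calls))
  co <- res$cooccurrence
  row <- co[co$event_a == "7p:gain" & co$event_b == "1p:loss", ]
  expect_equal(row$k, 0)
  expect_equal(row$direction, "exclusivity")
  expect_lt(row$p, 0.001)
  pos <- co[co$event_a == "7p:gain" & co$event_b == "7q:gain", ]
  expect_equal(pos$direction, "enrichment")
  expect_lt(pos$p, 0.001)
})

test_that("injected focal segments trigger the gap exclusion by construction", {
  arms <- build_arm_model(toy_cytobands("7"))
  calls <- matrix(0L, 2, 2, dimnames = list(c("F1", "F2"), arms$name))
  seg <- simulate_segment_tables(calls, arms, noise_sigma = 0,
                                 focal_rate = 1, seed = 23,
                                 focal_magnitude = 2, focal_fraction = 0.2)
  pr <- summarize_arms(seg, arms)
  flt <- filter_samples(pr, gap_threshold = 0.2)
  expect_equal(length(flt$retained), 0)

  seg2 <- simulate_segment_tables(calls, arms, noise_sigma = 0, seed = 23)
  expect_identical(seg2,
                   simulate_segment_tables(calls, arms, noise_sigma = 0,
                                           seed = 23))
})
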