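#' Load a copy-number segment table (SEG format)
#'
#' Parses the tab-separated SEG dialect (header row; Sample, Chromosome,
#' Start, End, optional Num_Probes, Segment_Mean). Chromosome names are
#' normalized so that "chr1" and "1" are the same key; coordinates are
#' normalized to 0-based half-open (SEG files are conventionally 1-based
#' inclusive). Segment values are log2(copy/2) ratios by default.
#'
#' @param path SEG file, or a data.frame with the same columns.
#' @param coords "one_based" (default; start is shifted down by 1) or
#'   "zero_based" (already half-open).
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `value`.
#' @export
load_segments <- function(path, coords = c("one_based", "zero_based")) {
  coords <- match.arg(coords)
  x <- if (is.data.frame(path)) path
       else utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(x))
  req <- c(sample = "sample", chrom = "chromosome", start = "start",
           end = "end")
  idx <- match(req, nm)
  vi <- which(nm %in% c("segment_mean", "value", "seg.mean"))[1]
  if (anyNA(idx) || is.na(vi))
    stop("missing required SEG column(s): ",
         paste(c(names(req)[is.na(idx)], if (is.na(vi)) "Segment_Mean"),
               collapse = ", "))
  seg <- data.frame(sample = as.character(x[[idx[1]]]),
                    chrom = sub("^chr", "", as.character(x[[idx[2]]])),
                    start = as.numeric(x[[idx[3]]]),
                    end = as.numeric(x[[idx[4]]]),
                    value = as.numeric(x[[vi]]),
                    stringsAsFactors = FALSE)
  if (coords == "one_based") seg$start <- seg$start - 1
  if (any(seg$start >= seg$end)) stop("segment(s) with start >= end")
  check_segment_overlaps(seg)
  seg
}

check_segment_overlaps <- function(seg) {
  offenders <- unlist(lapply(split(seg, paste(seg$sample, seg$chrom)),
    function(s) {
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        paste(s$sample[1], s$chrom[1]) else NULL
    }))
  if (length(offenders))
    stop("overlapping segments within sample/chromosome: ",
         paste(offenders, collapse = "; "))
  invisible(seg)
}

#' Build a chromosome-arm model from a cytoband file
#'
#' p-arm = union of bands named p*, q-arm = union of q*; centromeric bands
#' (stain "acen") are excluded from both. Acrocentric chromosomes with no
#' p bands get an absent p-arm.
#'
#' @param path UCSC-style cytoband file (chrom, start, end, band name,
#'   stain; no header), or an equivalent data.frame.
#' @return data.frame with columns `chrom`, `arm` ("p"/"q"), `start`, `end`
#'   and arm name `name` ("1p", "1q", ...). Absent p-arms are omitted.
#' @export
build_arm_model <- function(path) {
  x <- if (is.data.frame(path)) path
       else utils::read.table(path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
  if (ncol(x) < 5) stop("cytoband file needs 5 columns")
  names(x)[1:5] <- c("chrom", "start", "end", "band", "stain")
  x$chrom <- sub("^chr", "", as.character(x$chrom))
  x <- x[x$stain != "acen", , drop = FALSE]
  res <- lapply(split(x, x$chrom), function(b) {
    rows <- lapply(c("p", "q"), function(a) {
      bb <- b[startsWith(b$band, a), , drop = FALSE]
      if (nrow(bb) == 0) return(NULL)
      data.frame(chrom = b$chrom[1], arm = a,
                 start = min(bb$start), end = max(bb$end),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  arms <- do.call(rbind, res)
  rownames(arms) <- NULL
  noq <- setdiff(unique(x$chrom), arms$chrom[arms$arm == "q"])
  if (length(noq))
    stop("chromosome(s) with no q bands: ", paste(noq, collapse = ", "))
  arms$name <- paste0(arms$chrom, arms$arm)
  arms
}

# weighted median with the lower value taken at an exact 50% boundary
weighted_median_lower <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  v[which(cw >= half - 1e-9 * sum(w))[1]]
}

#' Summarize segment values over chromosome arms
#'
#' Intersects each sample's segments with each arm interval and reports the
#' length-weighted mean and the length-weighted median of the segment values
#' (the value at the 50% cumulative-overlap point, taking the lower value at
#' an exact boundary). Their absolute difference (`gap`) flags arms whose
#' level is driven by large focal events rather than a whole-arm shift.
#' Arms with zero coverage in a sample are marked missing.
#'
#' @param segments data.frame from [load_segments()].
#' @param arms data.frame from [build_arm_model()].
#' @return data.frame with `sample`, `arm`, `weighted_mean`,
#'   `weighted_median`, `gap`, `covered_fraction`, `missing`.
#' @export
summarize_arms <- function(segments, arms) {
  samples <- unique(segments$sample)
  grid <- expand.grid(sample = samples, i = seq_len(nrow(arms)),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    smp <- grid$sample[g]; a <- arms[grid$i[g], ]
    s <- segments[segments$sample == smp & segments$chrom == a$chrom, ,
                  drop = FALSE]
    ov_start <- pmax(s$start, a$start)
    ov_end <- pmin(s$end, a$end)
    keep <- ov_end > ov_start
    s <- s[keep, , drop = FALSE]
    w <- (ov_end - ov_start)[keep]
    if (nrow(s) == 0) {
      data.frame(sample = smp, arm = a$name, weighted_mean = NA_real_,
                 weighted_median = NA_real_, gap = NA_real_,
                 covered_fraction = 0, missing = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      wm <- sum(s$value * w) / sum(w)
      wmed <- weighted_median_lower(s$value, w)
      data.frame(sample = smp, arm = a$name, weighted_mean = wm,
                 weighted_median = wmed, gap = abs(wm - wmed),
                 covered_fraction = sum(w) / (a$end - a$start),
                 missing = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Exclude samples with large focal insertions or deletions
#'
#' A sample is excluded when any of its arms has a mean-median gap exceeding
#' `gap_threshold` (strict inequality: a gap exactly at the threshold is
#' retained). Such arms indicate large sub-arm events that would corrupt an
#' arm-level karyotype.
#'
#' @param profiles data.frame from [summarize_arms()].
#' @param gap_threshold default 0.2.
#' @return list with `retained` (character vector of sample ids) and
#'   `excluded` (data.frame of offending sample/arm/gap rows).
#' @export
filter_samples <- function(profiles, gap_threshold = 0.2) {
  bad <- profiles[!profiles$missing & profiles$gap > gap_threshold, ,
                  drop = FALSE]
  retained <- setdiff(unique(profiles$sample), unique(bad$sample))
  list(retained = retained,
       excluded = bad[, c("sample", "arm", "gap")])
}

#' Call arm-level aberrations from arm profiles
#'
#' +1 when the length-weighted mean is at or above `call_threshold`, -1 at or
#' below the negative threshold, else 0 (thresholds inclusive). Missing arms
#' give NA.
#'
#' @param profiles data.frame from [summarize_arms()] (typically restricted
#'   to filtered samples).
#' @param call_threshold default 0.2 (log2-ratio units).
#' @return integer matrix, samples x arms, values -1/0/+1 (NA = missing).
#' @export
call_arm_aberrations <- function(profiles, call_threshold = 0.2) {
  samples <- unique(profiles$sample)
  arm_names <- unique(profiles$arm)
  m <- matrix(NA_integer_, length(samples), length(arm_names),
              dimnames = list(samples, arm_names))
  call1 <- function(x) {
    if (is.na(x)) NA_integer_
    else if (x >= call_threshold) 1L
    else if (x <= -call_threshold) -1L
    else 0L
  }
  for (i in seq_len(nrow(profiles)))
    m[profiles$sample[i], profiles$arm[i]] <-
      call1(profiles$weighted_mean[i])
  m
}

#' Retain samples with complex aneuploidy (two or more arm aberrations)
#'
#' @param calls matrix from [call_arm_aberrations()].
#' @return character vector of retained sample ids.
#' @export
filter_complex <- function(calls) {
  n_ab <- rowSums(calls != 0, na.rm = TRUE)
  rownames(calls)[n_ab >= 2]
}

#' Arms aberrant in more than a minimum fraction of samples
#'
#' @param calls matrix from [call_arm_aberrations()].
#' @param min_fraction display cutoff (default 0.10); strict inequality.
#' @return character vector of arm names.
#' @export
frequent_arms <- function(calls, min_fraction = 0.10) {
  frac <- colMeans(calls != 0, na.rm = TRUE)
  frac[is.nan(frac)] <- 0
  colnames(calls)[frac > min_fraction]
}

#' Arm-level co-occurrence analysis of a tumor cohort
#'
#' End-to-end Fig-style analysis: summarize arms, exclude samples with large
#' focal events, call aberrations, keep complex karyotypes, and run the
#' pairwise hypergeometric co-occurrence tests on direction-specific arm
#' events.
#'
#' @param segments data.frame from [load_segments()].
#' @param arms data.frame from [build_arm_model()].
#' @param gap_threshold mean-median exclusion gap (default 0.2).
#' @param call_threshold aberration call threshold (default 0.2).
#' @param min_fraction display filter (default 0.10).
#' @param stat passed to [pairwise_cooccurrence()].
#' @return list with `calls` (retained samples x arms), `frequent_arms`,
#'   `cooccurrence` (pair statistics), `excluded` (gap report) and
#'   `profiles`.
#' @export
tumor_arm_analysis <- function(segments, arms, gap_threshold = 0.2,
                               call_threshold = 0.2, min_fraction = 0.10,
                               stat = "point") {
  profiles <- summarize_arms(segments, arms)
  flt <- filter_samples(profiles, gap_threshold)
  keep <- profiles$sample %in% flt$retained
  calls <- call_arm_aberrations(profiles[keep, , drop = FALSE], call_threshold)
  complex_samples <- filter_complex(calls)
  calls <- calls[complex_samples, , drop = FALSE]
  calls0 <- calls
  calls0[is.na(calls0)] <- 0L
  co <- if (nrow(calls0) >= 2 && ncol(aneuploidy_events(calls0 + 2L, 2L)) >= 2)
    pairwise_cooccurrence(calls0 + 2L, ploidy = 2L, stat = stat)
  else NULL
  list(calls = calls, frequent_arms = frequent_arms(calls0, min_fraction),
       cooccurrence = co, excluded = flt$excluded, profiles = profiles)
}
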