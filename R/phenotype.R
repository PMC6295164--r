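#' Doubling time from an optical-density growth curve
#'
#' Least-squares fit of ln(OD) against time; during exponential growth the
#' slope is the specific growth rate, so the doubling time is ln(2)/slope.
#' All points are used (no outlier rejection). The fit R-squared is reported
#' so poor exponential fits can be flagged downstream.
#'
#' @param time_h time points in hours, strictly increasing, length >= 3.
#' @param od optical densities at 600 nm, positive.
#' @return list with `doubling_time_h`, `growth_rate` (per hour), and
#'   `r_squared`.
#' @export
doubling_time <- function(time_h, od) {
  if (length(time_h) < 3 || length(od) != length(time_h))
    stop("need >= 3 matched (time, OD) points")
  if (any(diff(time_h) <= 0)) stop("time points must be strictly increasing")
  if (any(od <= 0)) stop("OD values must be positive")
  fit <- stats::lm(log(od) ~ time_h)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("no exponential growth: fitted slope <= 0")
  y <- log(od)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(doubling_time_h = log(2) / slope,
       growth_rate = slope,
       r_squared = r2)
}

#' Chromosome copy number from qPCR cycle thresholds (modified delta-delta-Ct)
#'
#' Duplicate C_t values are averaged; per strain, delta-C_t is the mean
#' target C_t minus the mean reference-primer C_t, converted to a fold
#' change 2^(-delta-C_t). The copy number of the target locus is the basal
#' ploidy times the ratio of the test strain's fold change to the wild-type
#' strain's. Plate offsets common to a strain's reactions cancel in
#' delta-C_t.
#'
#' @param test data.frame with columns `primer`, `role` ("target" or
#'   "reference") and `ct` for the test strain; duplicate rows per primer
#'   are averaged.
#' @param wildtype same layout for the wild-type (euploid) control strain.
#' @param basal_ploidy 1 or 2.
#' @return data.frame with one row per target primer: `primer`,
#'   `fold_test`, `fold_wt`, `copy_number`.
#' @export
qpcr_copy_number <- function(test, wildtype, basal_ploidy = 1L) {
  delta_ct <- function(d) {
    ref <- d$ct[d$role == "reference"]
    if (length(ref) == 0) stop("no reference-primer measurements supplied")
    targets <- d[d$role == "target", , drop = FALSE]
    if (nrow(targets) == 0) stop("no target-primer measurements supplied")
    mt <- tapply(targets$ct, targets$primer, mean)
    mt - mean(ref)
  }
  dt_test <- delta_ct(test)
  dt_wt <- delta_ct(wildtype)
  shared <- intersect(names(dt_test), names(dt_wt))
  if (length(shared) == 0)
    stop("test and wild-type strains share no target primers")
  fold_test <- 2^(-dt_test[shared])
  fold_wt <- 2^(-dt_wt[shared])
  data.frame(primer = shared,
             fold_test = unname(fold_test),
             fold_wt = unname(fold_wt),
             copy_number = basal_ploidy * unname(fold_test / fold_wt),
             stringsAsFactors = FALSE)
}
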