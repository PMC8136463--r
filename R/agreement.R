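#' Bias and precision of signed deviations
#'
#' Bias is the arithmetic mean of the signed deviations; precision is
#' their sample SD (n - 1 denominator).
#'
#' @param devs numeric vector of signed deviations, mm.
#' @return named numeric `c(bias_mm, precision_sd_mm)`.
#' @export
bias_and_precision <- function(devs) {
  devs <- devs[!is.na(devs)]
  if (length(devs) < 2L) .stopf("need at least 2 deviations")
  c(bias_mm = mean(devs), precision_sd_mm = stats::sd(devs))
}

#' Quantiles of absolute deviations
#'
#' Quantiles of `|devs|` at the 50th (median), 80th, 90th and 95th
#' percentiles by default, using linear interpolation between order
#' statistics (R's default type-7 convention).
#'
#' @param devs numeric vector of signed deviations.
#' @param probs probabilities.
#' @return named numeric vector of quantiles.
#' @export
abs_quantiles <- function(devs, probs = c(0.5, 0.8, 0.9, 0.95)) {
  devs <- devs[!is.na(devs)]
  if (!length(devs)) .stopf("no deviations supplied")
  stats::quantile(abs(devs), probs = probs, type = 7)
}

#' Cumulative error curve
#'
#' The empirical cumulative distribution of absolute deviations: sorted
#' `|dev|` against cumulative fraction `i/n`.  [curve_quantile()] reads
#' the curve at a probability using the same interpolation convention as
#' [abs_quantiles()], so the two agree at every probability.
#'
#' @param devs numeric vector of signed deviations.
#' @return data frame of class `error_curve` with columns `fraction`
#'   (nondecreasing, ending at 1) and `abs_dev_mm` (nondecreasing).
#' @export
cumulative_error_curve <- function(devs) {
  devs <- devs[!is.na(devs)]
  if (!length(devs)) .stopf("no deviations supplied")
  a <- sort(abs(devs))
  structure(data.frame(fraction = seq_along(a) / length(a),
                       abs_dev_mm = a),
            class = c("error_curve", "data.frame"))
}

#' @rdname cumulative_error_curve
#' @param curve an `error_curve`.
#' @param p probability in \[0, 1\].
#' @export
curve_quantile <- function(curve, p) {
  unname(stats::quantile(curve$abs_dev_mm, probs = p, type = 7))
}

#' Intraclass correlation for absolute agreement, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC of a
#' subjects-by-raters matrix (typically frames in rows, the method and
#' the consensus reference in two columns), with the F-based 95%
#' confidence interval of McGraw & Wong.  Mean squares are computed
#' directly from the two-way layout:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings numeric matrix or data frame, n subjects x k raters,
#'   complete rows only (rows with `NA` are dropped).
#' @param conf_level confidence level of the interval.
#' @return list with `icc`, `ci_low`, `ci_high` (clipped to \[-1, 1\]),
#'   `n`, `k`.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  ns <- nrow(m); nr <- ncol(m)
  if (ns < 3L) .stopf("need at least 3 complete rows; got %d", ns)
  if (nr < 2L) .stopf("need at least 2 raters")
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  if (sum((m - gm)^2) == 0) .stopf("zero total variance; ICC undefined")
  MSr <- nr * sum((rowm - gm)^2) / (ns - 1)
  MSc <- ns * sum((colm - gm)^2) / (nr - 1)
  MSe <- sum((m - outer(rowm, rep(1, nr)) -
                outer(rep(1, ns), colm) + gm)^2) /
    ((ns - 1) * (nr - 1))
  icc <- (MSr - MSe) / (MSr + (nr - 1) * MSe + nr * (MSc - MSe) / ns)
  alpha <- 1 - conf_level
  a <- (nr * icc) / (ns * (1 - icc))
  b <- 1 + (nr * icc * (ns - 1)) / (ns * (1 - icc))
  v <- (a * MSc + b * MSe)^2 /
    ((a * MSc)^2 / (nr - 1) + (b * MSe)^2 / ((ns - 1) * (nr - 1)))
  FL <- stats::qf(1 - alpha / 2, ns - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, ns - 1)
  lo <- (ns * (MSr - FL * MSe)) /
    (FL * (nr * MSc + (nr * ns - nr - ns) * MSe) + ns * MSr)
  hi <- (ns * (FU * MSr - MSe)) /
    (nr * MSc + (nr * ns - nr - ns) * MSe + ns * FU * MSr)
  list(icc = icc, ci_low = max(-1, min(lo, icc)),
       ci_high = min(1, max(hi, icc)), n = ns, k = nr)
}

#' Variance-ratio F test between two SDs
#'
#' `F = var(a) / var(b)` with a two-sided p value from the F distribution
#' on (nA-1, nB-1) degrees of freedom, as computed by `stats::var.test`.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
f_test_sd <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    .stopf("both samples need n >= 2")
  if (stats::var(b) == 0) .stopf("zero variance in denominator sample")
  vt <- stats::var.test(a, b)
  list(statistic = unname(vt$statistic), p_value = vt$p.value,
       df = unname(vt$parameter))
}

#' Wilcoxon signed-rank test on paired absolute errors
#'
#' Compares two paired samples of absolute deviations (their differences
#' follow a folded-normal-like, non-Gaussian distribution, hence a rank
#' test).  Zero differences are dropped; the null distribution is exact
#' for up to 25 informative pairs and a continuity-corrected normal
#' approximation above that.
#'
#' @param abs_a,abs_b paired numeric samples (same frames, same order).
#' @return list with `statistic` (V), `p_value`, `n` (informative
#'   pairs).
#' @export
wilcoxon_abs_errors <- function(abs_a, abs_b) {
  if (length(abs_a) != length(abs_b)) .stopf("samples must be paired")
  ok <- !is.na(abs_a) & !is.na(abs_b)
  d <- abs_a[ok] - abs_b[ok]
  n <- sum(d != 0)
  if (n == 0L) .stopf("all paired differences are zero")
  wt <- suppressWarnings(
    stats::wilcox.test(abs_a[ok], abs_b[ok], paired = TRUE,
                       exact = n <= 25L, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n)
}

#' Agreement summaries stratified by method, dimension and phase
#'
#' For each (method, dimension, phase in {ED, ES, pooled}) stratum of a
#' deviation table: n, bias, precision SD, the 50/80/90/95% quantiles of
#' absolute deviation, and ICC(2,1) of the method against the reference
#' with its 95% CI.  Strata with fewer than 2 deviations are marked
#' unavailable; ICC entries are `NA` when fewer than 3 complete pairs or
#' no between-frame variance exist.
#'
#' @param deviations a deviation table ([signed_deviations()] output,
#'   possibly several methods row-bound).
#' @return data frame, one row per stratum.
#' @export
stratified_summaries <- function(deviations) {
  .check_cols(deviations, c("frame_id", "method_id", "phase", "dimension",
                            "measurement_mm", "reference_mm",
                            "signed_deviation_mm"), "deviations")
  combos <- expand.grid(method_id = unique(deviations$method_id),
                        dimension = unique(deviations$dimension),
                        phase = c("ED", "ES", "pooled"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- deviations[deviations$method_id == combos$method_id[i] &
                      deviations$dimension == combos$dimension[i], ,
                    drop = FALSE]
    if (combos$phase[i] != "pooled")
      s <- s[s$phase == combos$phase[i], , drop = FALSE]
    base <- data.frame(combos[i, ], n = nrow(s), bias_mm = NA_real_,
                       precision_sd_mm = NA_real_, q50_mm = NA_real_,
                       q80_mm = NA_real_, q90_mm = NA_real_,
                       q95_mm = NA_real_, icc = NA_real_,
                       icc_ci_low = NA_real_, icc_ci_high = NA_real_,
                       available = FALSE, stringsAsFactors = FALSE)
    if (nrow(s) < 2L) return(base)
    bp <- bias_and_precision(s$signed_deviation_mm)
    q <- abs_quantiles(s$signed_deviation_mm)
    base$bias_mm <- bp[["bias_mm"]]
    base$precision_sd_mm <- bp[["precision_sd_mm"]]
    base$q50_mm <- q[[1]]; base$q80_mm <- q[[2]]
    base$q90_mm <- q[[3]]; base$q95_mm <- q[[4]]
    icc <- tryCatch(
      icc_absolute_agreement(cbind(s$measurement_mm, s$reference_mm)),
      error = function(e) NULL)
    if (!is.null(icc)) {
      base$icc <- icc$icc
      base$icc_ci_low <- icc$ci_low
      base$icc_ci_high <- icc$ci_high
    }
    base$available <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
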