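#' Match detected events to true events
#'
#' Greedy one-to-one nearest matching of detected event indices to true
#' event indices within a sample tolerance: all candidate pairs closer than
#' the tolerance are sorted by absolute distance and assigned greedily, each
#' event matching at most once. Unmatched true events count as misses (FN),
#' unmatched detections as false alarms (FP).
#'
#' @param true_indices,detected_indices Strictly increasing integer vectors
#'   of 1-based sample indices.
#' @param tolerance_samples Non-negative matching tolerance in samples.
#' @return Object of class `match_counts`: list with integers `TP`, `FN`,
#'   `FP` satisfying `TP + FN = length(true_indices)` and
#'   `TP + FP = length(detected_indices)`.
#' @export
match_events <- function(true_indices, detected_indices, tolerance_samples) {
  if (is.unsorted(true_indices, strictly = TRUE) ||
      is.unsorted(detected_indices, strictly = TRUE))
    stop_validation("event index lists must be strictly increasing")
  if (tolerance_samples < 0)
    stop_validation("tolerance must be >= 0")
  nt <- length(true_indices)
  nd <- length(detected_indices)
  tp <- 0L
  if (nt > 0L && nd > 0L) {
    d <- abs(outer(true_indices, detected_indices, "-"))
    pairs <- which(d <= tolerance_samples, arr.ind = TRUE)
    if (nrow(pairs)) {
      pairs <- pairs[order(d[pairs]), , drop = FALSE]
      used_t <- logical(nt)
      used_d <- logical(nd)
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1L]
        j <- pairs[p, 2L]
        if (!used_t[i] && !used_d[j]) {
          used_t[i] <- TRUE
          used_d[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  structure(list(TP = tp, FN = nt - tp, FP = nd - tp), class = "match_counts")
}

#' Critical success index
#'
#' `CSI = TP / (TP + FN + FP)`, scoring event detection in [0, 1]: 1 for
#' perfect detection, 0 when nothing is correctly detected.
#'
#' @param counts A `match_counts` (see [match_events()]) or a list with
#'   elements `TP`, `FN`, `FP`.
#' @return CSI in [0, 1].
#' @export
csi <- function(counts) {
  denom <- counts$TP + counts$FN + counts$FP
  if (denom <= 0) stop_degenerate("CSI undefined: no events at all")
  counts$TP / denom
}

#' Absolute error between reference and estimated respiratory rates
#'
#' @param reference_rr,estimated_rr Rates in BPM (finite, non-negative).
#' @return `|reference_rr - estimated_rr|` in BPM (vectorized).
#' @export
absolute_error <- function(reference_rr, estimated_rr) {
  if (!all(is.finite(reference_rr)) || !all(is.finite(estimated_rr)))
    stop_validation("rates must be finite")
  if (any(reference_rr < 0) || any(estimated_rr < 0))
    stop_validation("rates must be non-negative")
  abs(reference_rr - estimated_rr)
}

#' Bland-Altman agreement summary
#'
#' Differences `d = estimate - reference` summarized by their mean, sample
#' standard deviation, limits of agreement `mean +/- 2 * sd` (multiplier
#' exactly 2, not 1.96), and the percentage of differences falling inside
#' the limits (inclusive).
#'
#' @param reference,estimate Equal-length numeric vectors, `n >= 3`.
#' @return Object of class `bland_altman`: list with `mean_diff`,
#'   `std_diff`, `loa_low`, `loa_high`, `pct_within`, `n`, and the
#'   per-observation `differences` and `means`.
#' @export
bland_altman <- function(reference, estimate) {
  if (length(reference) != length(estimate))
    stop_validation("reference and estimate must have the same length")
  n <- length(reference)
  if (n < 3L) stop_validation("Bland-Altman needs at least 3 pairs")
  d <- estimate - reference
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 2 * s
  hi <- m + 2 * s
  structure(list(mean_diff = m, std_diff = s, loa_low = lo, loa_high = hi,
                 pct_within = 100 * mean(d >= lo & d <= hi), n = n,
                 differences = d, means = (estimate + reference) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d, mean diff %.3f, LOA [%.3f, %.3f], %.1f%% within\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high, x$pct_within))
  invisible(x)
}

#' Paired-samples t-test between reference and estimated rates
#'
#' Standard paired t statistic with `n - 1` degrees of freedom and a
#' two-sided p-value (via [stats::t.test()]). Degenerate difference vectors
#' are handled by convention: all-zero differences give `t = 0`, `p = 1`;
#' identical nonzero differences (zero variance, nonzero mean) are flagged
#' `degenerate` with an infinite statistic and `p = 0`.
#'
#' @param reference,estimate Equal-length numeric vectors, `n >= 2`.
#' @return List with `statistic`, `dof`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_t_test <- function(reference, estimate) {
  if (length(reference) != length(estimate))
    stop_validation("reference and estimate must have the same length")
  n <- length(reference)
  if (n < 2L) stop_validation("paired t-test needs at least 2 pairs")
  d <- estimate - reference
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, dof = n - 1L, p_value = 1,
                  mean_diff = 0, degenerate = FALSE))
    return(list(statistic = sign(mean(d)) * Inf, dof = n - 1L, p_value = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(estimate, reference, paired = TRUE)
  list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}
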