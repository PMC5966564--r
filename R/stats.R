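#' Default region-of-interest map
#'
#' Partition of the optodes into contiguous regions of interest across the
#' prefrontal headband.  The 16-optode profile maps optodes 1-4, 5-8,
#' 9-12, 13-16 to ROIs 1-4; the 4-optode profile maps each optode to its
#' own ROI.  Other optode counts divisible by 4 are split into 4 equal
#' contiguous blocks; otherwise each optode is its own ROI.
#'
#' @param profile An [fnirs_profile()].
#' @return Named list: ROI id -> integer vector of optode indices
#'   (disjoint, covering all optodes).
#' @export
default_roi_map <- function(profile) {
  n <- profile$n_optodes
  if (n %% 4 == 0 && n > 4) {
    per <- n / 4
    stats::setNames(lapply(1:4, function(r) ((r - 1) * per + 1):(r * per)),
                    as.character(1:4))
  } else {
    stats::setNames(lapply(seq_len(n), identity), as.character(seq_len(n)))
  }
}

#' Spatially average a stream over regions of interest
#'
#' Unweighted mean across the optodes of each ROI, per chromophore, per
#' sample.  The result is a [hemo_stream()] whose "optodes" are the ROIs,
#' in map order.
#'
#' @param stream A [hemo_stream()].
#' @param map ROI map as from [default_roi_map()].
#' @return A [hemo_stream()] with one column per ROI.
#' @export
roi_average <- function(stream, map) {
  stopifnot(inherits(stream, "hemo_stream"))
  all_opt <- sort(unlist(map))
  if (any(all_opt > ncol(stream$hbo)))
    stop("ROI map references optode ", max(all_opt),
         " but the stream has only ", ncol(stream$hbo), call. = FALSE)
  avg <- function(m) vapply(map, function(idx)
    rowMeans(m[, idx, drop = FALSE]), numeric(nrow(m)))
  hemo_stream(stream$time, avg(stream$hbo), avg(stream$hhb),
              sampling_rate = stream$sampling_rate)
}

#' Per-trial peak response
#'
#' The canonical trial-level activation statistic: the peak of the
#' (filtered) signal within the trial window (`[onset, onset + window)`,
#' half-open) minus the mean over the 2 s immediately before onset.
#' The peak is the sample deviating most in magnitude from the pre-onset
#' mean, kept signed — for the positive-going oxygenated response this is
#' simply the window maximum minus the pre-onset mean; for the
#' negative-going deoxygenated response it captures the trough.  Computed
#' per channel (ROI or optode) and chromophore.
#'
#' @param stream A [hemo_stream()] (typically ROI-averaged, MACD-filtered).
#' @param trial One protocol row (needs `onset_s`, `trial_index`).
#' @param trial_window_s Window length in seconds (default 30).
#' @param pre_s Pre-onset averaging window in seconds (default 2).
#' @return Data frame: `trial_index`, `channel`, `chromophore`, `value`.
#' @export
peak_response <- function(stream, trial, trial_window_s = 30, pre_s = 2) {
  stopifnot(inherits(stream, "hemo_stream"))
  onset <- as.numeric(trial$onset_s)
  pre <- stream$time >= onset - pre_s & stream$time < onset
  post <- stream$time >= onset & stream$time < onset + trial_window_s
  if (!any(pre) || min(stream$time) > onset - pre_s)
    stop("stream does not cover the ", pre_s,
         " s pre-trial window of trial ", trial$trial_index, call. = FALSE)
  if (!any(post))
    stop("no samples in the trial window of trial ", trial$trial_index,
         call. = FALSE)
  one <- function(m, chrom) {
    pre_mean <- colMeans(m[pre, , drop = FALSE])
    dev <- sweep(m[post, , drop = FALSE], 2, pre_mean)
    peak <- vapply(seq_len(ncol(dev)), function(j)
      dev[which.max(abs(dev[, j])), j], numeric(1))
    data.frame(
      trial_index = as.integer(trial$trial_index),
      channel = seq_len(ncol(m)),
      chromophore = chrom,
      value = peak,
      row.names = NULL)
  }
  rbind(one(stream$hbo, "hbo"), one(stream$hhb, "hhb"))
}

#' Mean and sample standard deviation of a set of values
#'
#' @param values Numeric vector, `n >= 1` (`sd` needs `n >= 2`).
#' @return List with `n`, `mean`, `sd` (sample sd, n-1 denominator).
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(is.na(values)))
    stop("`values` must be a nonempty numeric vector without NAs",
         call. = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Cohen's d from group summaries
#'
#' Standardized difference of two group means using the pooled standard
#' deviation with (n-1) weights:
#' `d = |m2 - m1| / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return Effect size (nonnegative); `Inf` with a warning when the pooled
#'   sd is zero but the means differ.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0",
                               call. = FALSE)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) {
    if (mean1 == mean2) return(0)
    warning("zero pooled sd with unequal means; effect size infinite",
            call. = FALSE)
    return(Inf)
  }
  abs(mean2 - mean1) / pooled
}

#' Two-sample unpaired t-test
#'
#' Thin wrapper over [stats::t.test()]: classic equal-variance two-sample
#' test by default (matching common usage in the applied literature), with
#' the Welch correction available.
#'
#' @param values1,values2 Numeric samples, each of length >= 2.
#' @param var_equal Pool variances (default TRUE).
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
unpaired_t_test <- function(values1, values2, var_equal = TRUE) {
  if (length(values1) < 2 || length(values2) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  if (stats::var(values1) == 0 && stats::var(values2) == 0)
    stop("both groups are degenerate (zero variance)", call. = FALSE)
  ht <- stats::t.test(values1, values2, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Minimum accuracy significantly above chance (exact binomial)
#'
#' Smallest accuracy `100 * k / n` whose exact binomial upper tail
#' `P(X >= k | n, p_chance)` does not exceed `alpha`.  For a balanced
#' two-class session of 20 trials at `alpha = 0.05` this is 75%; for 10
#' trials it is 90% — chance-level bars for small-sample classifier
#' evaluation.
#'
#' @param n_trials Number of test trials, >= 1.
#' @param p_chance Per-trial chance probability (default 0.5).
#' @param alpha Significance level in (0, 1]; `alpha = 1` returns 0.
#' @return Threshold accuracy in percent.
#' @export
binomial_chance_threshold <- function(n_trials, p_chance = 0.5,
                                      alpha = 0.05) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  for (k in 0:n_trials) {
    tail <- stats::pbinom(k - 1, n_trials, p_chance, lower.tail = FALSE)
    if (tail <= alpha) return(100 * k / n_trials)
  }
  100  # alpha smaller than P(X = n): only a perfect score qualifies
}
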