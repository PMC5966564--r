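#' Generate a constrained random trial sequence
#'
#' Draws an ordered sequence of load labels (`"low"` / `"high"`, `n_per_class`
#' of each) uniformly over the set of sequences satisfying two constraints:
#' when `first_block_balanced` is set, the first half of the sequence
#' contains equal counts of each class (required so the training phase sees
#' both classes equally often); and no label repeats on more than `max_run`
#' successive trials.  Uniformity over the constrained space is obtained by
#' rejection sampling from uniformly random balanced permutations, which is
#' cheap because the space is small.
#'
#' @param n_per_class Trials per class, >= 1.
#' @param first_block_balanced Logical; balance the first half.
#' @param max_run Longest permitted run of one label (default 2).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param max_tries Rejection-sampling cap before declaring the constraint
#'   set unsatisfiable.
#' @return Character vector of length `2 * n_per_class`.
#' @export
generate_trial_sequence <- function(n_per_class, first_block_balanced = TRUE,
                                    max_run = 2, seed, max_tries = 100000L) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (max_run < 1) stop("`max_run` must be >= 1", call. = FALSE)
  set.seed(seed)
  labels <- rep(c("low", "high"), each = n_per_class)
  n <- length(labels)
  for (i in seq_len(max_tries)) {
    cand <- sample(labels)
    if (sequence_valid(cand, first_block_balanced, max_run)) return(cand)
  }
  stop("could not draw a sequence satisfying the constraints in ",
       max_tries, " tries; the constraint set may be unsatisfiable",
       call. = FALSE)
}

# Constraint predicate shared by the generator and its tests.  For an odd
# first-block length exact balance is impossible; floor/ceiling counts
# are accepted instead.
sequence_valid <- function(labels, first_block_balanced = TRUE, max_run = 2) {
  n <- length(labels)
  if (first_block_balanced) {
    half <- labels[seq_len(n %/% 2)]
    if (abs(sum(half == "high") - length(half) / 2) > 0.5) return(FALSE)
  }
  r <- rle(labels)
  all(r$lengths <= max_run)
}

#' Lay out a session timeline
#'
#' Builds the session protocol from an ordered label sequence: a rest
#' baseline, then back-to-back trials of `trial_window_s` seconds separated
#' by `inter_trial_gap_s` of rest, so
#' `onset(k) = baseline_s + (k-1) * (trial_window_s + inter_trial_gap_s)`.
#' The first half of the trials is the labeled data-gathering phase (A),
#' the second half the online testing phase (C); classifier training
#' (phase B) happens between them and occupies no protocol time of its own.
#'
#' @param sequence Character vector of `"low"`/`"high"` labels (may be
#'   empty for a baseline-only protocol).
#' @param baseline_s Rest baseline duration before trial 1 (default 10).
#' @param trial_window_s Trial window anchored at message onset (default 30).
#' @param response_window_s Response window inside the trial (default 18;
#'   timeline metadata only, segmentation does not use it).
#' @param inter_trial_gap_s Rest after each trial window (default 5).
#' @return Object of class `session_protocol`: a data frame with columns
#'   `trial_index`, `load`, `onset_s`, `phase`, plus timing attributes.
#' @export
build_timeline <- function(sequence, baseline_s = 10, trial_window_s = 30,
                           response_window_s = 18, inter_trial_gap_s = 5) {
  if (baseline_s < 0 || trial_window_s <= 0 || inter_trial_gap_s < 0 ||
      response_window_s <= 0)
    stop("timing durations must be positive (gaps may be zero)", call. = FALSE)
  if (response_window_s > trial_window_s)
    stop("response window cannot exceed the trial window", call. = FALSE)
  n <- length(sequence)
  onsets <- baseline_s + (seq_len(n) - 1) * (trial_window_s + inter_trial_gap_s)
  phase <- rep(NA_character_, n)
  if (n > 0) phase <- ifelse(seq_len(n) <= n / 2, "A", "C")
  trials <- data.frame(
    trial_index = seq_len(n),
    load = as.character(sequence),
    onset_s = onsets,
    phase = phase,
    stringsAsFactors = FALSE
  )
  structure(trials,
            class = c("session_protocol", "data.frame"),
            baseline_s = baseline_s,
            trial_window_s = trial_window_s,
            response_window_s = response_window_s,
            inter_trial_gap_s = inter_trial_gap_s)
}

#' Total session duration implied by a protocol (seconds)
#' @param protocol A [build_timeline()] protocol.
#' @return Length of the session in seconds, including the final gap.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "session_protocol"))
  n <- nrow(protocol)
  attr(protocol, "baseline_s") +
    n * (attr(protocol, "trial_window_s") + attr(protocol, "inter_trial_gap_s"))
}

#' Cut one trial out of a filtered stream
#'
#' Extracts the samples with `onset <= t < onset + trial_window` (half-open
#' window, 0-based sample indexing from the window start) into a trial
#' tensor of dimension `n_optodes x 2 x round(trial_window * fs)`, with the
#' chromophore axis ordered hbo, hhb.  The stream must cover
#' `[onset - 2 s, onset + trial_window]` so that the pre-trial context used
#' by peak-response statistics is guaranteed to exist.
#'
#' @param filtered A [hemo_stream()] (typically MACD-filtered).
#' @param trial One row of a `session_protocol` (list or single-row data
#'   frame with `trial_index`, `load`, `onset_s`).
#' @param profile An [fnirs_profile()].
#' @param trial_window_s Trial window length in seconds (default 30).
#' @return Object of class `trial_tensor`: numeric array
#'   `n_optodes x 2 x n_samples` with attributes `load`, `trial_index`,
#'   `onset_s`.
#' @export
segment_trial <- function(filtered, trial, profile, trial_window_s = 30) {
  stopifnot(inherits(filtered, "hemo_stream"),
            inherits(profile, "fnirs_profile"))
  onset <- as.numeric(trial$onset_s)
  fs <- profile$sampling_rate
  n_expect <- as.integer(round(trial_window_s * fs))
  if (ncol(filtered$hbo) != profile$n_optodes)
    stop("stream has ", ncol(filtered$hbo), " optodes but profile expects ",
         profile$n_optodes, call. = FALSE)
  if (min(filtered$time) > onset - 2 ||
      max(filtered$time) < onset + trial_window_s - 1 / fs) {
    stop("stream does not cover trial ", trial$trial_index,
         " (needs [", onset - 2, ", ", onset + trial_window_s, "])",
         call. = FALSE)
  }
  idx <- which(filtered$time >= onset & filtered$time < onset + trial_window_s)
  if (length(idx) != n_expect)
    stop("trial ", trial$trial_index, ": found ", length(idx),
         " samples in the window, expected ", n_expect,
         "; is the stream uniformly sampled?", call. = FALSE)
  tens <- array(NA_real_, dim = c(profile$n_optodes, 2L, n_expect),
                dimnames = list(NULL, c("hbo", "hhb"), NULL))
  tens[, 1, ] <- t(filtered$hbo[idx, , drop = FALSE])
  tens[, 2, ] <- t(filtered$hhb[idx, , drop = FALSE])
  structure(tens, class = "trial_tensor",
            load = as.character(trial$load),
            trial_index = as.integer(trial$trial_index),
            onset_s = onset)
}
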