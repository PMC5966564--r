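#' Write / read a hemoglobin stream as long-format CSV
#'
#' Columns: `time_s`, `optode` (1-based), `chromophore` (`hbo`/`hhb`),
#' `value_umol_l`.  A write-then-read round trip preserves values to full
#' double precision (values are printed with 17 significant digits) and
#' sample order exactly.
#'
#' @param stream A [hemo_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hemo_csv <- function(stream, path) {
  stopifnot(inherits(stream, "hemo_stream"))
  n <- nrow(stream$hbo); p <- ncol(stream$hbo)
  df <- data.frame(
    time_s = rep(stream$time, times = 2 * p),
    optode = rep(rep(seq_len(p), each = n), times = 2),
    chromophore = rep(c("hbo", "hhb"), each = n * p),
    value_umol_l = c(as.vector(stream$hbo), as.vector(stream$hhb))
  )
  df$time_s <- sprintf("%.17g", df$time_s)
  df$value_umol_l <- sprintf("%.17g", df$value_umol_l)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hemo_csv
#' @param profile Optional [fnirs_profile()]; when given, the optode count
#'   is validated against it and its sampling rate is attached.
#' @param sampling_rate Sampling rate to record on the stream when no
#'   profile is given; inferred from the median timestamp spacing if NULL.
#' @return `read_hemo_csv()`: a [hemo_stream()].
#' @export
read_hemo_csv <- function(path, profile = NULL, sampling_rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "optode", "chromophore", "value_umol_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("stream CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$chromophore %in% c("hbo", "hhb"))
  if (length(bad))
    stop("row ", bad[1], ", column chromophore: invalid value '",
         df$chromophore[bad[1]], "'", call. = FALSE)
  p <- max(df$optode)
  if (!setequal(unique(df$optode), seq_len(p)))
    stop("optode indices must be 1..", p, " with no gaps", call. = FALSE)
  if (!is.null(profile) && p != profile$n_optodes)
    stop("stream has ", p, " optodes but the profile expects ",
         profile$n_optodes, call. = FALSE)
  time <- sort(unique(df$time_s))
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  pick <- function(chrom) {
    sub <- df[df$chromophore == chrom, ]
    if (nrow(sub) != length(time) * p)
      stop("incomplete ", chrom, " grid: expected ", length(time) * p,
           " rows, found ", nrow(sub), call. = FALSE)
    # rows may arrive in any order; index into the (time, optode) grid
    m <- matrix(NA_real_, length(time), p)
    m[cbind(match(sub$time_s, time), sub$optode)] <- sub$value_umol_l
    if (anyNA(m)) stop("duplicate or missing (time, optode) cells for ",
                       chrom, call. = FALSE)
    m
  }
  fs <- if (!is.null(profile)) profile$sampling_rate
        else if (!is.null(sampling_rate)) sampling_rate
        else 1 / stats::median(diff(time))
  hemo_stream(time, pick("hbo"), pick("hhb"), sampling_rate = fs)
}

#' Write / read a raw optical stream as long-format CSV
#'
#' Columns: `time_s`, `optode`, `wavelength_nm`, `intensity`.
#'
#' @param stream An [optical_stream()].
#' @param path CSV path.
#' @param wavelengths Wavelength labels for the two intensity planes.
#' @return `path` invisibly; `read_optical_csv()` returns an
#'   [optical_stream()].
#' @export
write_optical_csv <- function(stream, path, wavelengths = c(730, 850)) {
  stopifnot(inherits(stream, "optical_stream"))
  d <- dim(stream$intensity)
  df <- data.frame(
    time_s = rep(stream$time, times = 2 * d[2]),
    optode = rep(rep(seq_len(d[2]), each = d[1]), times = 2),
    wavelength_nm = rep(wavelengths, each = d[1] * d[2]),
    intensity = c(as.vector(stream$intensity[, , 1]),
                  as.vector(stream$intensity[, , 2]))
  )
  df$time_s <- sprintf("%.17g", df$time_s)
  df$intensity <- sprintf("%.17g", df$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_optical_csv
#' @export
read_optical_csv <- function(path, profile = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "optode", "wavelength_nm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("optical CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  wl <- sort(unique(df$wavelength_nm))
  if (length(wl) != 2L)
    stop("expected exactly 2 wavelengths, found ", length(wl), call. = FALSE)
  p <- max(df$optode)
  if (!is.null(profile) && p != profile$n_optodes)
    stop("stream has ", p, " optodes but the profile expects ",
         profile$n_optodes, call. = FALSE)
  time <- sort(unique(df$time_s))
  inten <- array(NA_real_, dim = c(length(time), p, 2L))
  for (w in 1:2) {
    sub <- df[df$wavelength_nm == wl[w], ]
    inten[cbind(match(sub$time_s, time), sub$optode, w)] <- sub$intensity
  }
  if (anyNA(inten)) stop("incomplete (time, optode, wavelength) grid",
                         call. = FALSE)
  optical_stream(time, inten)
}

#' Write / read a trial-event CSV
#'
#' Columns: `trial_index`, `onset_s`, `load` (`low`/`high`).
#'
#' @param protocol A `session_protocol` (for writing).
#' @param path CSV path.
#' @return `read_events_csv()` returns a data frame with those columns.
#' @export
write_events_csv <- function(protocol, path) {
  utils::write.csv(
    data.frame(trial_index = protocol$trial_index,
               onset_s = protocol$onset_s, load = protocol$load),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "onset_s", "load")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("events CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$load %in% c("low", "high"))
  if (length(bad))
    stop("row ", bad[1], ", column load: invalid value '", df$load[bad[1]],
         "'", call. = FALSE)
  if (any(diff(df$onset_s) <= 0))
    stop("trial onsets must be strictly increasing", call. = FALSE)
  df[, need]
}

#' Rebuild a session protocol from a trial-event table
#'
#' @param events Data frame from [read_events_csv()].
#' @param baseline_s,trial_window_s,response_window_s Timing constants.
#' @return A `session_protocol` with the recorded onsets.
#' @export
protocol_from_events <- function(events, baseline_s = 10,
                                 trial_window_s = 30,
                                 response_window_s = 18) {
  gap <- if (nrow(events) > 1)
    stats::median(diff(events$onset_s)) - trial_window_s else 5
  proto <- build_timeline(events$load, baseline_s = baseline_s,
                          trial_window_s = trial_window_s,
                          response_window_s = response_window_s,
                          inter_trial_gap_s = max(gap, 0))
  proto$onset_s <- events$onset_s
  proto$trial_index <- events$trial_index
  proto
}

#' Causal sample iterator over a stream
#'
#' Wraps a [hemo_stream()] in a closure that yields one sample (timestamp
#' plus the per-optode values) per call, in time order, so downstream
#' consumers can never observe future samples.  Replay speed does not
#' affect the values: paced and as-fast-as-possible replays produce
#' identical sequences.
#'
#' @param stream A [hemo_stream()].
#' @param real_time Sleep between samples to mimic acquisition pacing
#'   (default FALSE: replay as fast as possible).
#' @return A function; each call returns `list(time, hbo, hhb)` or `NULL`
#'   when the stream is exhausted.
#' @export
stream_player <- function(stream, real_time = FALSE) {
  stopifnot(inherits(stream, "hemo_stream"))
  i <- 0L
  n <- length(stream$time)
  function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    if (real_time && i > 1L)
      Sys.sleep(max(0, stream$time[i] - stream$time[i - 1L]))
    list(time = stream$time[i],
         hbo = stream$hbo[i, ], hhb = stream$hhb[i, ])
  }
}

#' Serialize a session result to JSON
#'
#' Captures per-trial predictions, the selected regularization, metrics
#' and provenance (package version, seeds, config echo) in a round-trip
#' friendly JSON report.
#'
#' @param result A [run_online_session()] result.
#' @param path Output JSON path.
#' @param seed Seed used for the session (provenance).
#' @param config Optional named list echoed into the report.
#' @return `path`, invisibly.
#' @export
write_session_report <- function(result, path, seed = NULL, config = NULL) {
  stopifnot(inherits(result, "session_result"))
  report <- list(
    package_version = as.character(utils::packageVersion("fnirsbci")),
    seed = seed,
    config = config,
    selected_C = result$classifier$selected_C,
    cv_accuracy = result$classifier$cv_accuracy,
    training_accuracy = result$classifier$training_accuracy,
    predictions = result$predictions,
    metrics = unclass(result$metrics)[c("accuracy", "precision",
                                        "recall", "f1")],
    skipped_trials = result$skipped
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Published per-subject classification tables
#'
#' Returns one of the two bundled machine-learning result tables
#' (per-subject training/testing accuracy, precision, recall and F1, in
#' percent) shipped as plain CSV under `extdata`: table `1` for the
#' 16-optode desktop-system sessions, table `2` for the 4-optode portable
#' sessions.
#'
#' @param which 1 or 2.
#' @return Data frame with columns `subject`, `accuracy_training`,
#'   `accuracy_testing`, `precision`, `recall`, `f1`.
#' @export
load_results_table <- function(which = 1) {
  stopifnot(which %in% c(1, 2))
  path <- system.file("extdata", sprintf("table%d.csv", which),
                      package = "fnirsbci", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
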