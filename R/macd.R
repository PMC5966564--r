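#' Exponential moving average state
#'
#' First-order recursive smoother over a window of `N` time points:
#' `y_n = 2/(N+1) * x_n + (N-1)/(N+1) * y_{n-1}`.  The smoothing weight
#' `alpha = 2/(N+1)` lies in (0, 1]; `N = 1` reproduces the input.  The
#' first output can be seeded either with the first input sample
#' (`init = "first"`, removes the startup transient so a constant stream is
#' a fixed point from sample one) or with zero (`init = "zero"`).
#'
#' @param n_window Window length `N` in time points, integer >= 1.
#' @param init `"first"` or `"zero"`.
#' @return Object of class `ema_state`.
#' @export
ema_state <- function(n_window, init = c("first", "zero")) {
  init <- match.arg(init)
  n_window <- as.integer(n_window)
  if (is.na(n_window) || n_window < 1L)
    stop("EMA window must be an integer >= 1", call. = FALSE)
  structure(
    list(n_window = n_window, alpha = 2 / (n_window + 1),
         last_output = if (init == "zero") 0 else NA_real_,
         initialized = (init == "zero"), init = init),
    class = "ema_state")
}

#' One EMA step
#'
#' Advances the recursive smoother by a single sample in O(1).  A constant
#' input is a fixed point (unit DC gain).
#'
#' @param state An [ema_state()].
#' @param x New sample value.
#' @return List with elements `state` (updated) and `y` (filtered value).
#' @export
ema_update <- function(state, x) {
  stopifnot(inherits(state, "ema_state"))
  y <- if (!state$initialized) x else
    state$alpha * x + (1 - state$alpha) * state$last_output
  state$last_output <- y
  state$initialized <- TRUE
  list(state = state, y = y)
}

#' One MACD step
#'
#' Difference between a short- and a long-window EMA driven by the same
#' input sample: a causal band-pass filter with zero DC gain.  Both states
#' must use the same initialization mode and have seen the same number of
#' samples.
#'
#' @param short,long [ema_state()] objects, `short$n_window < long$n_window`.
#' @param x New sample value.
#' @return List with `short`, `long` (updated states) and `y` (MACD value).
#' @export
macd_update <- function(short, long, x) {
  if (short$init != long$init || short$initialized != long$initialized)
    stop("short and long EMA states must share initialization", call. = FALSE)
  if (short$n_window >= long$n_window)
    stop("short window must be shorter than long window", call. = FALSE)
  s <- ema_update(short, x)
  l <- ema_update(long, x)
  list(short = s$state, long = l$state, y = s$y - l$y)
}

#' MACD filter configuration
#'
#' Window lengths are specified in seconds and converted to time points as
#' `N = round(window_s * fs)` — 6 s / 13 s give 12 / 26 points at 2 Hz and
#' 24 / 52 points at 4 Hz.
#'
#' @param short_window_s Short EMA window in seconds (default 6).
#' @param long_window_s Long EMA window in seconds (default 13).
#' @param sampling_rate Sampling rate in Hz.
#' @param init Initialization mode passed to [ema_state()].
#' @return Object of class `macd_config`.
#' @export
macd_config <- function(short_window_s = 6, long_window_s = 13,
                        sampling_rate, init = c("first", "zero")) {
  init <- match.arg(init)
  if (short_window_s <= 0 || long_window_s <= 0)
    stop("window lengths must be positive", call. = FALSE)
  if (short_window_s >= long_window_s)
    stop("short window must be shorter than long window", call. = FALSE)
  n_short <- max(1L, as.integer(round(short_window_s * sampling_rate)))
  n_long <- as.integer(round(long_window_s * sampling_rate))
  if (n_short >= n_long)
    stop("windows too close for this sampling rate: short and long collapse ",
         "to ", n_short, " and ", n_long, " points", call. = FALSE)
  structure(list(short_window_s = short_window_s,
                 long_window_s = long_window_s,
                 sampling_rate = sampling_rate,
                 n_short = n_short, n_long = n_long, init = init),
            class = "macd_config")
}

# Batch EMA over a whole vector; identical to iterating ema_update().
# stats::filter's `init` seeds y_0, so y_1 = alpha*x_1 + (1-alpha)*y_0
# matches the recurrence exactly.  C-level loop, causal.
ema_filter_vec <- function(x, n_window, init = "first") {
  alpha <- 2 / (n_window + 1)
  y0 <- if (init == "first") x[1] else 0
  as.numeric(stats::filter(alpha * x, filter = 1 - alpha,
                           method = "recursive", init = y0))
}

#' Apply the MACD band-pass filter to every channel of a stream
#'
#' Filters each (optode, chromophore) channel independently and causally:
#' the output at sample n depends only on samples 1..n.  Output has the
#' same length as the input.  Requires uniform sampling at the configured
#' rate (timestamps checked to `tol` seconds).
#'
#' @param stream A [hemo_stream()].
#' @param config A [macd_config()].
#' @param tol Tolerance on timestamp spacing in seconds.
#' @param allow_gaps Permit dropped samples (spacing larger than one
#'   period); the recursion then simply continues across the gap, as an
#'   online consumer of a lossy stream would.  Oversampling is still
#'   rejected.  Default FALSE: strictly uniform sampling required.
#' @return A filtered [hemo_stream()].
#' @export
filter_stream <- function(stream, config, tol = 1e-6, allow_gaps = FALSE) {
  stopifnot(inherits(stream, "hemo_stream"), inherits(config, "macd_config"))
  dt <- 1 / config$sampling_rate
  d <- diff(stream$time)
  bad <- if (allow_gaps) any(d < dt - tol) else any(abs(d - dt) > tol)
  if (length(stream$time) > 1L && bad)
    stop("stream is not uniformly sampled at ", config$sampling_rate,
         " Hz (within tolerance)", call. = FALSE)
  macd_one <- function(x)
    ema_filter_vec(x, config$n_short, config$init) -
      ema_filter_vec(x, config$n_long, config$init)
  hemo_stream(
    stream$time,
    apply(stream$hbo, 2, macd_one),
    apply(stream$hhb, 2, macd_one),
    sampling_rate = stream$sampling_rate
  )
}

#' Closed-form frequency response of the MACD filter
#'
#' The EMA with weight `alpha` has transfer function
#' `H(f) = alpha / (1 - (1-alpha) exp(-i 2 pi f / fs))`; the MACD response
#' is the difference of the short- and long-window responses.  Returns the
#' gain magnitude.  At DC both EMAs have unit gain, so `|H(0)| = 0`
#' exactly; the magnitude rises to an interior maximum (the pass band,
#' roughly 0.02-0.33 Hz for the 6 s / 13 s windows at 2 Hz) and decays
#' toward Nyquist.
#'
#' @param config A [macd_config()].
#' @param f Frequencies in Hz, `0 <= f <= fs/2`.
#' @return Numeric vector of gain magnitudes.
#' @export
frequency_response <- function(config, f) {
  stopifnot(inherits(config, "macd_config"))
  if (any(f < 0) || any(f > config$sampling_rate / 2))
    stop("frequencies must lie in [0, fs/2]", call. = FALSE)
  # 1 - (1-a)e^{-iw} written as a + (1-a)(1 - e^{-iw}) so that the DC
  # gain of each EMA is exactly 1 and the MACD gain exactly 0 at f = 0.
  H <- function(n_window) {
    alpha <- 2 / (n_window + 1)
    w <- 2 * pi * f / config$sampling_rate
    alpha / (alpha + (1 - alpha) * (1 - exp(-1i * w)))
  }
  Mod(H(config$n_short) - H(config$n_long))
}
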