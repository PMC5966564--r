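#' Canonical gamma-shaped hemodynamic response kernel
#'
#' Unit-peak single-gamma impulse response
#' `h(t) = ((t - d)/p)^(p/s) * exp(-((t - d) - p)/s)` for `t >= d`, written
#' so that the peak value is exactly 1 at `d + p` (onset delay plus
#' time-to-peak).  With the defaults (no delay, 6 s to peak, dispersion
#' 1 s) the response has decayed to ~1e-5 by 25 s, comfortably inside a
#' 30 s trial window.
#'
#' @param t Time since stimulus onset, seconds, `t >= 0`.
#' @param onset_delay_s Latency before the response starts (default 0).
#' @param time_to_peak_s Time from response start to peak (default 6).
#' @param dispersion_s Width parameter, > 0 (default 1).
#' @return Numeric vector of kernel values in `[0, 1]`.
#' @export
hrf_kernel <- function(t, onset_delay_s = 0, time_to_peak_s = 6,
                       dispersion_s = 1) {
  if (dispersion_s <= 0) stop("`dispersion_s` must be > 0", call. = FALSE)
  if (time_to_peak_s <= 0) stop("`time_to_peak_s` must be > 0", call. = FALSE)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  tt <- t - onset_delay_s
  k <- time_to_peak_s / dispersion_s   # shape - 1 of the gamma form
  out <- numeric(length(t))
  pos <- tt > 0
  out[pos] <- (tt[pos] / time_to_peak_s)^k *
    exp(-(tt[pos] - time_to_peak_s) / dispersion_s)
  out
}

#' Synthetic session configuration
#'
#' Parameters of the generative model used to emulate a prefrontal fNIRS
#' working-memory session.  Each trial adds
#' `amp(load) * spatial_gain[optode] * hrf(t - onset)` to the oxygenated
#' hemoglobin of every optode; deoxygenated hemoglobin carries the
#' opposite-signed response scaled by `hhb_ratio`.  On top of the evoked
#' response sit the classic physiological nuisance components: white
#' sensor noise, a per-channel linear drift, and cardiac (~1.1 Hz),
#' respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz) oscillations with
#' random per-channel phases.
#'
#' Default amplitudes (low 0.5, high 2.0 umol/L, a 4:1 contrast on a
#' subset of optodes) and noise levels are chosen so that per-session
#' classification accuracy falls in the 50-100% range typical of
#' single-trial prefrontal workload classification.
#'
#' @param profile An [fnirs_profile()].
#' @param amp_low,amp_high Evoked HbO2 peak amplitude (umol/L) for low /
#'   high load; `amp_high >= amp_low >= 0`.
#' @param hhb_ratio Ratio of the (negative) hHb response to the HbO2
#'   response (default 1/3).
#' @param onset_delay_s,time_to_peak_s,dispersion_s [hrf_kernel()] shape.
#' @param noise_white,noise_cardiac,noise_resp,noise_mayer Amplitudes in
#'   umol/L (white = sd; oscillations = sine amplitude).
#' @param f_cardiac,f_resp,f_mayer Oscillation frequencies in Hz.
#' @param drift_span Maximum absolute linear drift over the whole session,
#'   umol/L; each channel draws a slope uniformly in `+/- drift_span`.
#' @param spatial_map Per-optode gain on the evoked response.  Default:
#'   gain 2 on the optodes of the anterior-prefrontal region of interest
#'   (ROI 2: optodes 5-8 of the 16-optode profile, optode 2 of the
#'   4-optode profile), gain 1 elsewhere, mimicking spatially focal
#'   activation.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(profile = profile_sim16(),
                             amp_low = 0.5, amp_high = 2.0,
                             hhb_ratio = 1 / 3,
                             onset_delay_s = 0, time_to_peak_s = 6,
                             dispersion_s = 1,
                             noise_white = 0.3,
                             noise_cardiac = 0.15, f_cardiac = 1.1,
                             noise_resp = 0.2, f_resp = 0.25,
                             noise_mayer = 0.3, f_mayer = 0.1,
                             drift_span = 0.5,
                             spatial_map = default_spatial_map(profile)) {
  stopifnot(inherits(profile, "fnirs_profile"))
  if (amp_low < 0 || amp_high < amp_low)
    stop("need amp_high >= amp_low >= 0", call. = FALSE)
  if (any(c(noise_white, noise_cardiac, noise_resp, noise_mayer,
            drift_span) < 0))
    stop("noise amplitudes must be >= 0", call. = FALSE)
  if (length(spatial_map) != profile$n_optodes)
    stop("`spatial_map` must have one gain per optode", call. = FALSE)
  structure(list(
    profile = profile, amp_low = amp_low, amp_high = amp_high,
    hhb_ratio = hhb_ratio, onset_delay_s = onset_delay_s,
    time_to_peak_s = time_to_peak_s, dispersion_s = dispersion_s,
    noise_white = noise_white,
    noise_cardiac = noise_cardiac, f_cardiac = f_cardiac,
    noise_resp = noise_resp, f_resp = f_resp,
    noise_mayer = noise_mayer, f_mayer = f_mayer,
    drift_span = drift_span, spatial_map = as.numeric(spatial_map)),
    class = "synthetic_config")
}

#' Default focal activation map
#'
#' Gain 2 on the optodes covering the anterior prefrontal region of
#' interest (ROI 2), gain 1 elsewhere; identity scaling when the profile's
#' optode count is not a multiple of 4.
#'
#' @param profile An [fnirs_profile()].
#' @return Numeric vector of per-optode gains.
#' @export
default_spatial_map <- function(profile) {
  gains <- rep(1, profile$n_optodes)
  rois <- default_roi_map(profile)
  if ("2" %in% names(rois)) gains[rois[["2"]]] <- 2
  gains
}

#' Simulate a complete fNIRS session
#'
#' Generates a hemoglobin stream over the whole protocol (baseline, trials,
#' gaps) from the generative model in [synthetic_config()], together with
#' its ground truth.  Reproducible: the same seed gives a bit-identical
#' stream.  Set `encode_optical = TRUE` to additionally return the stream
#' encoded as raw two-wavelength intensities via the forward modified
#' Beer-Lambert model (for end-to-end tests of the optical front end).
#'
#' @param protocol A [build_timeline()] protocol.
#' @param config A [synthetic_config()].
#' @param seed Integer seed; mandatory.
#' @param encode_optical Also produce raw intensities (default FALSE).
#' @param baseline_intensity Raw intensity level about which the optical
#'   encoding oscillates (arbitrary detector units).
#' @return List of class `synthetic_session`: `stream` ([hemo_stream()]),
#'   `truth` (list with `labels` and `peaks`, the noiseless per-trial peak
#'   response per optode and chromophore), and when requested `optical`
#'   (an [optical_stream()]) and `baseline` (its [baseline_record()]).
#' @export
simulate_session <- function(protocol, config, seed,
                             encode_optical = FALSE,
                             baseline_intensity = 1000) {
  stopifnot(inherits(protocol, "session_protocol"),
            inherits(config, "synthetic_config"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  profile <- config$profile
  fs <- profile$sampling_rate
  n_opt <- profile$n_optodes
  dur <- protocol_duration(protocol)
  n <- as.integer(round(dur * fs))
  time <- (seq_len(n) - 1) / fs

  # Noiseless evoked response, shared across channels up to spatial gain.
  evoked <- numeric(n)
  for (i in seq_len(nrow(protocol))) {
    amp <- if (protocol$load[i] == "high") config$amp_high else config$amp_low
    rel <- time - protocol$onset_s[i]
    on <- rel >= 0
    evoked[on] <- evoked[on] +
      amp * hrf_kernel(rel[on], config$onset_delay_s,
                       config$time_to_peak_s, config$dispersion_s)
  }
  hbo_clean <- outer(evoked, config$spatial_map)         # n x n_opt
  hhb_clean <- -config$hhb_ratio * hbo_clean

  set.seed(seed)
  add_noise <- function(clean) {
    noise <- matrix(stats::rnorm(n * n_opt, sd = config$noise_white),
                    n, n_opt)
    for (o in seq_len(n_opt)) {
      ph <- stats::runif(3, 0, 2 * pi)
      noise[, o] <- noise[, o] +
        config$noise_cardiac * sin(2 * pi * config$f_cardiac * time + ph[1]) +
        config$noise_resp    * sin(2 * pi * config$f_resp    * time + ph[2]) +
        config$noise_mayer   * sin(2 * pi * config$f_mayer   * time + ph[3]) +
        stats::runif(1, -config$drift_span, config$drift_span) * time / dur
    }
    clean + noise
  }
  hbo <- add_noise(hbo_clean)
  hhb <- add_noise(hhb_clean)
  stream <- hemo_stream(time, hbo, hhb, sampling_rate = fs)

  # Ground truth: labels plus noiseless peak response per trial/optode.
  tw <- attr(protocol, "trial_window_s")
  peaks <- NULL
  if (nrow(protocol) > 0) {
    peak1 <- max(hrf_kernel(seq(0, tw, by = 1 / fs), config$onset_delay_s,
                            config$time_to_peak_s, config$dispersion_s))
    amps <- ifelse(protocol$load == "high", config$amp_high, config$amp_low)
    peaks <- list(
      hbo = outer(amps * peak1, config$spatial_map),
      hhb = -config$hhb_ratio * outer(amps * peak1, config$spatial_map))
  }
  truth <- list(labels = protocol$load, peaks = peaks)

  out <- list(stream = stream, truth = truth)
  if (encode_optical) {
    dod <- mbll_forward(hbo, hhb, profile)
    inten <- array(NA_real_, dim = c(n, n_opt, 2L))
    inten[, , 1] <- baseline_intensity * 10^(-dod$dod_1)
    inten[, , 2] <- baseline_intensity * 10^(-dod$dod_2)
    out$optical <- optical_stream(time, inten)
    out$baseline <- structure(
      matrix(baseline_intensity, n_opt, 2L),
      class = "baseline_record", window = c(0, attr(protocol, "baseline_s")))
  }
  structure(out, class = "synthetic_session")
}

#' Rebuild a protocol with a freshly drawn label sequence
#'
#' Keeps the timing of `protocol` (baseline, windows, gaps, trial count)
#' but redraws the constrained load sequence from `seed`.
#'
#' @param protocol A `session_protocol` template.
#' @param seed Integer seed for [generate_trial_sequence()].
#' @return A new `session_protocol`.
#' @export
reseed_protocol <- function(protocol, seed) {
  n <- nrow(protocol)
  labels <- generate_trial_sequence(n %/% 2, seed = seed)
  build_timeline(labels,
                 baseline_s = attr(protocol, "baseline_s"),
                 trial_window_s = attr(protocol, "trial_window_s"),
                 response_window_s = attr(protocol, "response_window_s"),
                 inter_trial_gap_s = attr(protocol, "inter_trial_gap_s"))
}

#' Sweep classification accuracy against effect size
#'
#' For each high-load amplitude in `amp_grid`, simulates `n_rep` fresh
#' seeded sessions, runs the full online pipeline (filter, segment, train
#' with cross-validated cost selection, classify) on each, and reports the
#' mean and standard deviation of phase-C accuracy.  Per-replicate
#' failures are recorded, not fatal.
#'
#' @param protocol A [build_timeline()] protocol.
#' @param config Base [synthetic_config()]; its `amp_high` is replaced by
#'   each grid value.
#' @param amp_grid Numeric vector of high-load amplitudes (umol/L).
#' @param n_rep Replicates per grid point.
#' @param seed Integer base seed; replicate r of grid point g uses a
#'   deterministic offset of it.
#' @param fresh_sequence Redraw the constrained trial-label sequence for
#'   every replicate from its seed (default TRUE), as each recorded
#'   session would; set FALSE to hold the supplied protocol's sequence
#'   fixed across replicates.
#' @param ... Passed to [run_online_session()].
#' @return Data frame: `amp_high`, `mean_accuracy`, `sd_accuracy`,
#'   `n_ok`, `n_failed`.
#' @export
effect_size_sweep <- function(protocol, config, amp_grid, n_rep = 20,
                              seed = 1, fresh_sequence = TRUE, ...) {
  if (length(amp_grid) == 0) stop("`amp_grid` must be nonempty", call. = FALSE)
  rows <- lapply(seq_along(amp_grid), function(g) {
    cfg <- config
    cfg$amp_high <- max(amp_grid[g], cfg$amp_low)
    accs <- rep(NA_real_, n_rep)
    for (r in seq_len(n_rep)) {
      s <- seed + 1000L * (g - 1L) + r
      accs[r] <- tryCatch({
        proto_r <- if (fresh_sequence) reseed_protocol(protocol, s) else
          protocol
        sess <- simulate_session(proto_r, cfg, seed = s)
        res <- run_online_session(sess$stream, proto_r, cfg$profile,
                                  seed = s, ...)
        res$metrics$accuracy
      }, error = function(e) NA_real_)
    }
    data.frame(amp_high = amp_grid[g],
               mean_accuracy = mean(accs, na.rm = TRUE),
               sd_accuracy = stats::sd(accs, na.rm = TRUE),
               n_ok = sum(!is.na(accs)), n_failed = sum(is.na(accs)))
  })
  do.call(rbind, rows)
}
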