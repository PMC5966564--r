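#' Optical intensity stream
#'
#' Container for raw two-wavelength optical intensities: `time` in seconds
#' from session start (strictly increasing) and `intensity`, a numeric array
#' of dimension `n_samples x n_optodes x 2` (third axis ordered as the
#' profile's wavelengths).  Intensities are in arbitrary detector units and
#' must be positive for valid frames.
#'
#' @param time Numeric vector of timestamps (s), strictly increasing.
#' @param intensity Array `n_samples x n_optodes x 2`.
#' @return An object of class `optical_stream`.
#' @export
optical_stream <- function(time, intensity) {
  intensity <- as.array(intensity)
  if (length(dim(intensity)) != 3L || dim(intensity)[3] != 2L)
    stop("`intensity` must be an n_samples x n_optodes x 2 array", call. = FALSE)
  if (length(time) != dim(intensity)[1])
    stop("`time` length must match the first dimension of `intensity`",
         call. = FALSE)
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  structure(list(time = as.numeric(time), intensity = intensity),
            class = "optical_stream")
}

#' Baseline intensity record
#'
#' Per-(optode, wavelength) mean raw intensity over a rest window recorded
#' before the first trial (10 s by convention).  All means must be positive.
#'
#' @param stream An [optical_stream()].
#' @param window Numeric pair `c(start, end)` in seconds; frames with
#'   `start <= time < end` enter the mean.  Default `c(0, 10)`.
#' @return Object of class `baseline_record`: a `n_optodes x 2` matrix of
#'   mean intensities with the window stored as an attribute.
#' @export
baseline_record <- function(stream, window = c(0, 10)) {
  stopifnot(inherits(stream, "optical_stream"), length(window) == 2L,
            window[2] > window[1])
  sel <- stream$time >= window[1] & stream$time < window[2]
  if (!any(sel))
    stop("baseline window [", window[1], ", ", window[2],
         ") contains no frames", call. = FALSE)
  m <- apply(stream$intensity[sel, , , drop = FALSE], c(2, 3), mean)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("baseline means must all be positive and finite", call. = FALSE)
  structure(m, class = "baseline_record", window = window)
}

#' Optical-density change relative to baseline
#'
#' Computes `dOD = -log10(I / I0)` for every (optode, wavelength) channel.
#' An intensity drop relative to baseline (more absorption) gives a positive
#' optical-density change; `I == I0` gives exactly zero.
#'
#' @param stream An [optical_stream()] (or a single frame as a
#'   `n_optodes x 2` matrix of intensities).
#' @param baseline A [baseline_record()] (or bare `n_optodes x 2` matrix).
#' @return Array of the same shape as the input intensities.
#' @export
od_change <- function(stream, baseline) {
  inten <- if (inherits(stream, "optical_stream")) stream$intensity else
    array(as.matrix(stream), dim = c(1L, dim(as.matrix(stream))))
  b <- unclass(baseline)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("baseline means must be positive", call. = FALSE)
  bad <- which(inten <= 0 | !is.finite(inten), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive intensity in frame ", bad[1, 1], ", optode ",
         bad[1, 2], ", wavelength index ", bad[1, 3], call. = FALSE)
  dod <- inten
  for (w in 1:2)
    dod[, , w] <- -log10(sweep(inten[, , w, drop = FALSE],
                               2, b[, w], "/")[, , 1, drop = FALSE])
  dod
}

#' Hemoglobin stream
#'
#' Baseline-relative concentration changes: `time` (s), and `hbo`/`hhb`,
#' each a `n_samples x n_optodes` matrix of oxy-/deoxy-hemoglobin changes
#' in umol/L.
#'
#' @param time Numeric timestamps (s), strictly increasing.
#' @param hbo,hhb Matrices `n_samples x n_optodes`, finite values.
#' @param sampling_rate Sampling rate in Hz (metadata; checked against
#'   `time` spacing by consumers that require uniform sampling).
#' @return Object of class `hemo_stream`.
#' @export
hemo_stream <- function(time, hbo, hhb, sampling_rate) {
  hbo <- as.matrix(hbo); hhb <- as.matrix(hhb)
  if (!identical(dim(hbo), dim(hhb)))
    stop("`hbo` and `hhb` must have identical dimensions", call. = FALSE)
  if (length(time) != nrow(hbo))
    stop("`time` length must equal the number of rows of `hbo`", call. = FALSE)
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(!is.finite(hbo)) || any(!is.finite(hhb)))
    stop("concentration values must be finite", call. = FALSE)
  structure(list(time = as.numeric(time), hbo = hbo, hhb = hhb,
                 sampling_rate = as.numeric(sampling_rate)),
            class = "hemo_stream")
}

#' @export
print.hemo_stream <- function(x, ...) {
  cat(sprintf("<hemo_stream> %d samples x %d optodes @ %g Hz (%.1f s)\n",
              nrow(x$hbo), ncol(x$hbo), x$sampling_rate,
              diff(range(x$time))))
  invisible(x)
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert law.  For each optode the 2x2 linear
#' system `dOD(lambda) = L * eps(lambda, chromophore) * dc` is solved, where
#' `L = separation(cm) * DPF` is the effective pathlength and `eps` the
#' molar extinction matrix of the profile.  Concentration changes are
#' returned in umol/L.  The map is linear: zero optical-density change gives
#' exactly zero concentration change, and the forward model is recovered by
#' inversion to numerical precision.
#'
#' @param dod_1,dod_2 Optical-density change at the first / second profile
#'   wavelength; matrices `n_samples x n_optodes` (vectors are treated as a
#'   single sample).
#' @param profile An [fnirs_profile()].
#' @return List with matrices `hbo` and `hhb` (umol/L), same shape as input.
#' @export
mbll_convert <- function(dod_1, dod_2, profile) {
  stopifnot(inherits(profile, "fnirs_profile"))
  dod_1 <- rbind(dod_1); dod_2 <- rbind(dod_2)
  if (!identical(dim(dod_1), dim(dod_2)))
    stop("the two optical-density inputs must have identical shape",
         call. = FALSE)
  L_cm <- profile$separation_mm / 10 * profile$dpf
  # dc (mol/L) = E^-1 %*% dOD / L; report umol/L
  Einv <- solve(profile$extinction)
  hbo <- (Einv[1, 1] * dod_1 + Einv[1, 2] * dod_2) / L_cm * 1e6
  hhb <- (Einv[2, 1] * dod_1 + Einv[2, 2] * dod_2) / L_cm * 1e6
  list(hbo = hbo, hhb = hhb)
}

#' Forward modified Beer-Lambert model
#'
#' Maps concentration changes (umol/L) to optical-density changes at the
#' profile's two wavelengths; the exact inverse of [mbll_convert()].  Used
#' to encode synthetic concentration streams as raw intensities and as the
#' round-trip oracle in tests.
#'
#' @param hbo,hhb Matrices `n_samples x n_optodes` in umol/L.
#' @inheritParams mbll_convert
#' @return List with matrices `dod_1`, `dod_2`.
#' @export
mbll_forward <- function(hbo, hhb, profile) {
  stopifnot(inherits(profile, "fnirs_profile"))
  hbo <- rbind(hbo); hhb <- rbind(hhb)
  L_cm <- profile$separation_mm / 10 * profile$dpf
  E <- profile$extinction
  list(
    dod_1 = (E[1, 1] * hbo + E[1, 2] * hhb) * 1e-6 * L_cm,
    dod_2 = (E[2, 1] * hbo + E[2, 2] * hhb) * 1e-6 * L_cm
  )
}

#' Convert a raw optical stream to a hemoglobin stream
#'
#' Convenience wrapper: optical-density change relative to the supplied
#' baseline followed by modified Beer-Lambert inversion, per frame.
#'
#' @param stream An [optical_stream()].
#' @param baseline A [baseline_record()].
#' @param profile An [fnirs_profile()].
#' @return A [hemo_stream()].
#' @export
optical_to_hemo <- function(stream, baseline, profile) {
  dod <- od_change(stream, baseline)
  cc <- mbll_convert(dod[, , 1, drop = TRUE], dod[, , 2, drop = TRUE], profile)
  hemo_stream(stream$time, rbind(cc$hbo), rbind(cc$hhb),
              sampling_rate = profile$sampling_rate)
}

#' Per-optode signal-quality flags
#'
#' Flags optodes whose raw intensity sits at the configured detector ceiling
#' or floor for more than `pinned_frac` of frames (saturated / occluded), or
#' whose intensity variance is below `dead_var` at every wavelength (dead
#' channel, e.g. a disconnected detector).
#'
#' @param stream An [optical_stream()].
#' @param profile An [fnirs_profile()].
#' @param ceiling,floor Detector range limits in raw units.
#' @param pinned_frac Fraction of frames at the limit that triggers a flag.
#' @param dead_var Variance threshold below which a channel counts as dead.
#' @return Data frame with columns `optode`, `status`
#'   (`"ok"`, `"saturated"`, `"dead"`).
#' @export
check_saturation <- function(stream, profile,
                             ceiling = 4095, floor = 0,
                             pinned_frac = 0.5, dead_var = 1e-12) {
  stopifnot(inherits(stream, "optical_stream"),
            inherits(profile, "fnirs_profile"))
  if (length(stream$time) == 0L)
    stop("empty stream", call. = FALSE)
  if (diff(range(stream$time)) < 2)
    stop("need at least 2 s of data to assess signal quality", call. = FALSE)
  n_opt <- dim(stream$intensity)[2]
  status <- character(n_opt)
  for (o in seq_len(n_opt)) {
    x1 <- stream$intensity[, o, 1]
    x2 <- stream$intensity[, o, 2]
    pin1 <- mean(x1 >= ceiling | x1 <= floor)
    pin2 <- mean(x2 >= ceiling | x2 <= floor)
    v <- max(stats::var(x1), stats::var(x2), na.rm = TRUE)
    status[o] <- if (max(pin1, pin2) > pinned_frac) "saturated"
      else if (v < dead_var) "dead"
      else "ok"
  }
  data.frame(optode = seq_len(n_opt), status = status)
}
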