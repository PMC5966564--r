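#' Device profile for a continuous-wave fNIRS sensor
#'
#' Describes the sensor geometry and acquisition settings needed to turn
#' optical-density changes into hemoglobin concentration changes: number of
#' optodes (source-detector channels), sampling rate, the two measurement
#' wavelengths, the source-detector separation and the differential
#' pathlength factor (DPF).  The effective photon pathlength used by the
#' modified Beer-Lambert law is `separation (cm) * dpf`.
#'
#' @param n_optodes Number of optodes (channels), a positive integer.
#' @param sampling_rate Sampling frequency in Hz.
#' @param wavelengths Numeric pair of distinct wavelengths in nm.
#' @param separation_mm Source-detector separation in mm.
#' @param dpf Differential pathlength factor (dimensionless).
#' @param extinction 2x2 numeric matrix of molar extinction coefficients in
#'   cm^-1 M^-1; rows are the two wavelengths (in the order of `wavelengths`),
#'   columns the chromophores `hbo` (oxygenated) and `hhb` (deoxygenated
#'   hemoglobin).  Defaults to [default_extinction()] evaluated at
#'   `wavelengths`.
#'
#' @return An object of class `fnirs_profile`.
#' @seealso [profile_sim16()], [profile_flight4()] for the two bundled
#'   presets, and [mbll_convert()] for how the profile is used.
#' @export
fnirs_profile <- function(n_optodes,
                          sampling_rate,
                          wavelengths = c(730, 850),
                          separation_mm = 25,
                          dpf = 5.97,
                          extinction = default_extinction(wavelengths)) {
  n_optodes <- as.integer(n_optodes)
  if (length(n_optodes) != 1L || is.na(n_optodes) || n_optodes < 1L)
    stop("`n_optodes` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  if (length(wavelengths) != 2L || wavelengths[1] == wavelengths[2])
    stop("`wavelengths` must be two distinct values (nm)", call. = FALSE)
  if (separation_mm <= 0) stop("`separation_mm` must be > 0", call. = FALSE)
  if (dpf <= 0) stop("`dpf` must be > 0", call. = FALSE)
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2L, 2L)))
    stop("`extinction` must be a 2x2 matrix (wavelength x chromophore)",
         call. = FALSE)
  if (kappa(extinction) > 1e8 || abs(det(extinction)) < .Machine$double.eps)
    stop("extinction matrix is singular or ill-conditioned; ",
         "check the configured coefficients", call. = FALSE)
  dimnames(extinction) <- list(paste0("wl", wavelengths), c("hbo", "hhb"))
  structure(
    list(
      n_optodes     = n_optodes,
      sampling_rate = as.numeric(sampling_rate),
      wavelengths   = as.numeric(wavelengths),
      separation_mm = as.numeric(separation_mm),
      dpf           = as.numeric(dpf),
      extinction    = extinction
    ),
    class = "fnirs_profile"
  )
}

#' @export
print.fnirs_profile <- function(x, ...) {
  cat(sprintf(
    "<fnirs_profile> %d optodes @ %g Hz, wavelengths %g/%g nm, sep %g mm, DPF %g\n",
    x$n_optodes, x$sampling_rate, x$wavelengths[1], x$wavelengths[2],
    x$separation_mm, x$dpf))
  invisible(x)
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxygenated (HbO2) and deoxygenated (hHb)
#' hemoglobin in cm^-1 M^-1, from the widely used spectrophotometric
#' compilation tabulated at 2 nm steps across the near-infrared window.
#' Vendor processing software may use a slightly different compilation;
#' concentration values scale accordingly (classification downstream is
#' invariant to a fixed per-channel linear rescaling).  Values are available
#' here for 730 and 850 nm only; supply your own matrix to [fnirs_profile()]
#' for other wavelengths.
#'
#' @param wavelengths Numeric pair of wavelengths in nm.
#' @return 2x2 matrix, rows = wavelengths, columns = c(hbo, hhb).
#' @export
default_extinction <- function(wavelengths = c(730, 850)) {
  tab <- rbind(
    "730" = c(hbo = 390.00, hhb = 1102.20),
    "850" = c(hbo = 1058.00, hhb = 691.32)
  )
  key <- as.character(round(wavelengths))
  if (!all(key %in% rownames(tab)))
    stop("no bundled extinction coefficients for wavelengths ",
         paste(wavelengths, collapse = "/"),
         " nm; supply an explicit `extinction` matrix", call. = FALSE)
  out <- tab[key, , drop = FALSE]
  rownames(out) <- paste0("wl", wavelengths)
  out
}

#' Bundled device presets
#'
#' `profile_sim16()` is a 16-optode headband sampling at 2 Hz (desktop
#' continuous-wave system); `profile_flight4()` is a miniaturized wireless
#' 4-optode band sampling at 4 Hz.  Both use 730/850 nm, 25 mm separation
#' and DPF 5.97.
#'
#' @return An `fnirs_profile`.
#' @export
profile_sim16 <- function() fnirs_profile(16L, 2)

#' @rdname profile_sim16
#' @export
profile_flight4 <- function() fnirs_profile(4L, 4)

#' Read a device profile from a YAML configuration file
#'
#' Expected keys: `n_optodes`, `fs_hz`, `wavelengths_nm` (pair),
#' `separation_mm`, `dpf`, and optionally `extinction_coeffs` (2x2,
#' row-major wavelength x chromophore).  Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return An `fnirs_profile`.
#' @export
read_profile_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_optodes", "fs_hz", "wavelengths_nm", "separation_mm", "dpf",
             "extinction_coeffs")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown profile keys in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  wl <- if (is.null(cfg$wavelengths_nm)) c(730, 850) else unlist(cfg$wavelengths_nm)
  ext <- if (is.null(cfg$extinction_coeffs)) default_extinction(wl) else
    matrix(unlist(cfg$extinction_coeffs), nrow = 2, byrow = TRUE)
  fnirs_profile(
    n_optodes     = cfg$n_optodes,
    sampling_rate = cfg$fs_hz,
    wavelengths   = wl,
    separation_mm = if (is.null(cfg$separation_mm)) 25 else cfg$separation_mm,
    dpf           = if (is.null(cfg$dpf)) 5.97 else cfg$dpf,
    extinction    = ext
  )
}
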