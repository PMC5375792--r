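# Spectrum subtraction: remove motion-artifact peaks from the PPG power
# spectra using the per-bin envelope of the acceleration power spectra, then
# apply a relative floor so only prominent residual peaks survive.

#' Normalize a spectrum to unit energy
#'
#' Scales a nonnegative spectrum so its sum of squared coefficients equals 1,
#' putting PPG and acceleration spectra on a common energy scale before
#' subtraction. An all-zero spectrum (rest window) is returned unchanged with
#' a warning.
#'
#' @param s nonnegative numeric spectrum.
#' @return rescaled spectrum.
#' @export
normalize_energy <- function(s) {
  e <- sum(s^2)
  if (e == 0) {
    warning("all-zero spectrum; energy normalization skipped (rest window?)")
    return(s)
  }
  s / sqrt(e)
}

#' Per-bin acceleration spectral envelope
#'
#' The elementwise maximum of the three (normalized) acceleration spectra over
#' bins `0..max_bin`: the bins where any accelerometer axis carries energy are
#' the bins where PPG motion artifact is expected.
#'
#' @param sx,sy,sz equal-length nonnegative spectra.
#' @param max_bin last analysis bin (0-based); `NULL` keeps full length.
#' @return envelope vector over bins `0..max_bin`.
#' @export
accel_envelope <- function(sx, sy, sz, max_bin = NULL) {
  if (length(sy) != length(sx) || length(sz) != length(sx)) {
    stop("acceleration spectra must have equal length")
  }
  env <- pmax(sx, sy, sz)
  if (!is.null(max_bin)) env <- env[seq_len(max_bin + 1L)]
  env
}

#' Subtract the acceleration envelope and apply the relative floor
#'
#' For each analysis bin, `d[l] = max(s_ppg[l] - acc_env[l], 0)`; with
#' `pmax = max(d)`, every coefficient strictly below `fraction * pmax`
#' (default 1/5) is zeroed. Coefficients exactly at the floor are kept.
#'
#' @param s_ppg unit-energy PPG power spectrum (bins `0..max_bin` used).
#' @param acc_env unit-energy acceleration envelope over the same bins.
#' @param fraction relative floor (default 0.2).
#' @param max_bin last analysis bin (0-based); defaults to
#'   `length(acc_env) - 1`.
#' @return list of class `clean_spectrum`: `s` (cleansed spectrum over bins
#'   `0..max_bin`), `pmax` (pre-floor maximum), `empty` (TRUE when the
#'   envelope swallowed everything; downstream falls back to prediction).
#' @export
subtract_and_threshold <- function(s_ppg, acc_env, fraction = 0.2,
                                   max_bin = length(acc_env) - 1L) {
  bins <- seq_len(max_bin + 1L)
  s <- s_ppg[bins]
  env <- acc_env[bins]
  if (length(env) < length(bins)) stop("acceleration envelope too short")
  d <- pmax(s - env, 0)
  pm <- max(d)
  if (pm == 0) {
    return(structure(list(s = d, pmax = 0, empty = TRUE),
                     class = "clean_spectrum"))
  }
  d[d < fraction * pm] <- 0
  structure(list(s = d, pmax = pm, empty = FALSE), class = "clean_spectrum")
}

#' Cleanse the two PPG spectra of one window
#'
#' Normalizes all five spectra to unit energy over the analysis bins, forms
#' the acceleration envelope, and subtracts it from each PPG spectrum with
#' the relative floor.
#'
#' @param s_ppg N x 2 PPG power spectra.
#' @param s_acc N x 3 acceleration power spectra on the same grid.
#' @param cfg a [default_config()] list (`max_bin`, `subtract_fraction`).
#' @return list with `s1`, `s2` ([subtract_and_threshold()] results) and
#'   `acc_env`.
#' @export
cleanse_window_spectra <- function(s_ppg, s_acc, cfg = default_config()) {
  bins <- seq_len(cfg$max_bin + 1L)
  norm_cut <- function(s) suppressWarnings(normalize_energy(s[bins]))
  p1 <- norm_cut(s_ppg[, 1L]); p2 <- norm_cut(s_ppg[, 2L])
  env <- accel_envelope(norm_cut(s_acc[, 1L]), norm_cut(s_acc[, 2L]),
                        norm_cut(s_acc[, 3L]), max_bin = cfg$max_bin)
  list(s1 = subtract_and_threshold(p1, env, cfg$subtract_fraction,
                                   cfg$max_bin),
       s2 = subtract_and_threshold(p2, env, cfg$subtract_fraction,
                                   cfg$max_bin),
       acc_env = env)
}
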