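#' Downsample a series by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth at 80% of
#' the target Nyquist) before keeping every `fs_in/fs_out`-th sample, so the
#' 125 Hz recordings become 25 Hz analysis streams.
#'
#' @param x numeric series.
#' @param fs_in input sampling rate, Hz.
#' @param fs_out output sampling rate, Hz; must divide `fs_in`.
#' @return numeric series of length `floor(length(x) / (fs_in/fs_out))`.
#' @export
downsample <- function(x, fs_in, fs_out) {
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9) {
    stop("unsupported rate: fs_in=", fs_in, " is not an integer multiple of ",
         "fs_out=", fs_out)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(x)
  cutoff <- 0.8 * (fs_out / 2) / (fs_in / 2)  # normalized to input Nyquist
  aa <- signal::butter(8, cutoff, type = "low")
  y <- signal::filtfilt(aa, x)
  n_out <- length(x) %/% factor
  y[seq.int(1L, by = factor, length.out = n_out)]
}

#' Band-pass filter a series (zero phase)
#'
#' Designs a Butterworth band-pass and applies it forward--backward
#' (zero-phase), so filtered PPG and acceleration channels keep their relative
#' timing. The analysis band 0.4--4 Hz brackets adult heart rates
#' (0.5--3 Hz) with margin for harmonics.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (2 by default).
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 0.4, high = 4, order = 2) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges out of range: need 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Plan sliding analysis windows
#'
#' Windows are `window_s` seconds long and advance by `shift_s` seconds
#' (8 s / 2 s by default, i.e. 6 s overlap), expressed as half-open 0-based
#' sample ranges at the analysis rate.
#'
#' @param T_samples total samples at `cfg$fs_target`.
#' @param cfg a [default_config()] list.
#' @return A list of class `window_plan` with `window_s`, `shift_s`,
#'   `fs_target` and `slices`, a matrix with columns `start`, `end`
#'   (half-open, 0-based).
#' @export
plan_windows <- function(T_samples, cfg = default_config()) {
  win <- as.integer(round(cfg$window_s * cfg$fs_target))
  hop <- as.integer(round(cfg$shift_s * cfg$fs_target))
  if (T_samples < win) {
    stop("record too short: ", T_samples, " samples < one ", cfg$window_s,
         " s window (", win, " samples)")
  }
  n <- (T_samples - win) %/% hop + 1L
  starts <- (seq_len(n) - 1L) * hop
  structure(list(window_s = cfg$window_s, shift_s = cfg$shift_s,
                 fs_target = cfg$fs_target,
                 slices = cbind(start = starts, end = starts + win)),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> %d windows of %g s, shift %g s @ %g Hz\n",
              nrow(x$slices), x$window_s, x$shift_s, x$fs_target))
  invisible(x)
}

#' Preprocess a session for analysis
#'
#' Downsamples every channel to the analysis rate, band-pass filters
#' (zero-phase Butterworth), and plans the sliding windows.
#'
#' @param record a [sensor_record()].
#' @param cfg a [default_config()] list.
#' @return list with `ppg` (2 x T'), `accel` (3 x T') at `fs_target`, and
#'   `plan`, the [plan_windows()] result.
#' @export
preprocess_record <- function(record, cfg = default_config()) {
  stopifnot(inherits(record, "sensor_record"))
  ds <- function(ch) downsample(ch, record$fs, cfg$fs_target)
  bp <- function(ch) bandpass(ch, cfg$fs_target, cfg$bp_low, cfg$bp_high,
                              cfg$bp_order)
  ppg <- t(apply(record$ppg, 1L, function(ch) bp(ds(ch))))
  accel <- t(apply(record$accel, 1L, function(ch) bp(ds(ch))))
  list(ppg = ppg, accel = accel,
       plan = plan_windows(ncol(ppg), cfg))
}
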