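# Synthetic treadmill sessions: a slowly ramping heart-rate trace following
# the rest/run/faster/repeat protocol, PPG channels built from cardiac
# harmonics plus accelerometer-coupled artifact plus noise, and acceleration
# channels built from a drifting cadence sinusoid plus noise.

#' Simulation configuration
#'
#' Defaults emulate a 300 s treadmill session: 30 s easy walking, two blocks
#' of running with increasing speed, a repeat cycle, and a slow-down, encoded
#' as continuous piecewise-linear heart-rate ramps between 80 and 168 BPM
#' (heart rate responds smoothly to the speed steps). Cadence
#' drifts inside 1.0--2.8 Hz and is kept at least about 0.3 Hz away from the
#' cardiac frequency unless the `crossing` stress scenario is requested.
#'
#' @param duration_s session length in seconds; the protocol ramps are scaled
#'   proportionally when this differs from the protocol's native length.
#' @param fs sampling rate (125 Hz).
#' @param hr_protocol list of `c(duration_s, bpm_start, bpm_end)` ramps.
#' @param cadence_hz_range allowed cadence band, Hz.
#' @param n_ppg_harmonics number of cardiac harmonics.
#' @param harmonic_amps harmonic amplitudes (decaying).
#' @param alpha artifact gain per PPG channel (scalar recycled to 2).
#' @param accel_noise_sd,ppg_noise_sd additive white noise levels.
#' @param coupling_matrix 2 x 3 mixing of acceleration channels into the PPG
#'   channels.
#' @param crossing when TRUE the cadence tracks the cardiac frequency exactly
#'   (the hard regime where motion and heart peaks collide).
#' @param seed RNG seed; the session is fully deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 300, fs = 125,
                       hr_protocol = list(c(30, 80, 85), c(60, 85, 125),
                                          c(60, 125, 160), c(30, 160, 135),
                                          c(30, 135, 150), c(60, 150, 168),
                                          c(30, 168, 130)),
                       cadence_hz_range = c(1.0, 2.8),
                       n_ppg_harmonics = 3,
                       harmonic_amps = c(1, 0.4, 0.2),
                       alpha = 1,
                       accel_noise_sd = 0.1,
                       ppg_noise_sd = 0.05,
                       coupling_matrix = rbind(c(0.8, 0.5, 0.3),
                                               c(0.4, 0.7, 0.5)),
                       crossing = FALSE,
                       seed = 1L) {
  bpms <- unlist(lapply(hr_protocol, function(x) x[2:3]))
  if (any(bpms < 40 | bpms > 230)) {
    stop("heart-rate protocol outside the 40-230 BPM physiologic range")
  }
  alpha <- rep_len(alpha, 2L)
  stopifnot(duration_s > 0, fs > 0, length(harmonic_amps) >= n_ppg_harmonics,
            all(alpha >= 0), accel_noise_sd >= 0, ppg_noise_sd >= 0,
            nrow(coupling_matrix) == 2L, ncol(coupling_matrix) == 3L)
  structure(list(duration_s = duration_s, fs = fs, hr_protocol = hr_protocol,
                 cadence_hz_range = cadence_hz_range,
                 n_ppg_harmonics = n_ppg_harmonics,
                 harmonic_amps = harmonic_amps, alpha = alpha,
                 accel_noise_sd = accel_noise_sd, ppg_noise_sd = ppg_noise_sd,
                 coupling_matrix = coupling_matrix, crossing = crossing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Instantaneous HR (BPM) at every raw sample, from the piecewise ramps.
protocol_hr <- function(scfg) {
  durs <- vapply(scfg$hr_protocol, `[`, 0, 1L)
  durs <- durs * scfg$duration_s / sum(durs)
  n_total <- round(scfg$duration_s * scfg$fs)
  hr <- numeric(0)
  for (i in seq_along(scfg$hr_protocol)) {
    n <- round(sum(durs[seq_len(i)]) * scfg$fs) - length(hr)
    seg <- scfg$hr_protocol[[i]]
    hr <- c(hr, seq(seg[2L], seg[3L], length.out = n))
  }
  rep_len(hr, n_total)
}

#' Simulate one treadmill session
#'
#' Builds the raw 125 Hz channels and the per-window ground truth (mean
#' instantaneous heart rate over each 8 s window under the 2 s-shift
#' convention, evaluated after downsampling to the analysis rate).
#'
#' @param scfg a [sim_config()].
#' @param cfg a [default_config()] pipeline configuration (for the windowing
#'   convention used to write ground truth).
#' @return A [sensor_record()] with `truth_bpm` filled.
#' @export
simulate_session <- function(scfg = sim_config(), cfg = default_config()) {
  stopifnot(inherits(scfg, "sim_config"))
  rng <- local_rng(scfg$seed)
  fs <- scfg$fs
  hr <- protocol_hr(scfg)
  n <- length(hr)
  t_idx <- seq_len(n) / fs
  f_card <- hr / 60
  # cadence: offset below the cardiac line, clipped into the allowed band,
  # with a slow +/-0.03 Hz drift; the crossing scenario locks it to f_card
  drift <- 0.03 * sin(2 * pi * t_idx / 60 + rng$unif(1, 0, 2 * pi))
  f_cad <- if (scfg$crossing) f_card else {
    pmin(pmax(f_card - 0.5, scfg$cadence_hz_range[1L]),
         scfg$cadence_hz_range[2L]) + drift
  }
  phase_cad <- 2 * pi * cumsum(f_cad) / fs
  axis_amp <- c(1, 0.9, 0.8)
  psi <- rng$unif(6, 0, 2 * pi)
  accel <- t(vapply(1:3, function(j) {
    axis_amp[j] * sin(phase_cad + psi[j]) +
      0.3 * axis_amp[j] * sin(2 * phase_cad + psi[3 + j]) +
      rng$norm(n, sd = scfg$accel_noise_sd)
  }, numeric(n)))
  phase_card <- 2 * pi * cumsum(f_card) / fs
  phi <- rng$unif(2 * scfg$n_ppg_harmonics, 0, 2 * pi)
  artifact <- scfg$coupling_matrix %*% accel
  ppg <- t(vapply(1:2, function(h) {
    cardiac <- Reduce(`+`, lapply(seq_len(scfg$n_ppg_harmonics), function(k) {
      scfg$harmonic_amps[k] *
        sin(k * phase_card + phi[(h - 1) * scfg$n_ppg_harmonics + k])
    }))
    cardiac + scfg$alpha[h] * artifact[h, ] +
      rng$norm(n, sd = scfg$ppg_noise_sd)
  }, numeric(n)))
  # ground truth per analysis window (after decimation to fs_target)
  dec <- round(fs / cfg$fs_target)
  plan <- plan_windows(n %/% dec, cfg)
  truth <- apply(plan$slices, 1L, function(sl) {
    mean(hr[(sl[1L] * dec + 1L):(sl[2L] * dec)])
  })
  sensor_record(ppg, accel, fs, truth_bpm = truth,
                subject_id = sprintf("sim-seed%d", scfg$seed))
}

#' Build a labeled training corpus from synthetic sessions
#'
#' Runs the pipeline through candidate discovery on each synthetic session,
#' computes the `(C, S)` features with the previous window's ground truth as
#' the reference frequency (teacher forcing), labels candidates against the
#' window's ground truth, and pools everything.
#'
#' @param n_sessions number of sessions (>= 1).
#' @param cfg a [default_config()].
#' @param seed base seed; session `i` uses `seed + i`.
#' @param alphas artifact gains cycled across sessions. The default spans the
#'   clean-to-strong operating range: clean sessions matter because they
#'   contribute "largest peak but far from the track" false examples (the
#'   coefficient-ratio feature makes every window's maximum look strong), and
#'   without them the classifier accepts distant spurious maxima.
#' @param duration_s per-session length, seconds.
#' @return data.frame with columns `C`, `S`, `label`, `session`, `window`.
#' @export
simulate_training_corpus <- function(n_sessions = 5L, cfg = default_config(),
                                     seed = cfg$seed,
                                     alphas = c(0, 0.5, 1, 1.5, 2),
                                     duration_s = 150) {
  if (n_sessions < 1L) stop("n_sessions must be at least 1")
  out <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    scfg <- sim_config(duration_s = duration_s,
                       alpha = alphas[((i - 1L) %% length(alphas)) + 1L],
                       seed = seed + i)
    rec <- simulate_session(scfg, cfg)
    aw <- analyze_windows(rec, cfg)
    truth <- rec$truth_bpm
    feats <- list()
    for (w in seq_along(aw$windows)[-1L]) {
      cands <- aw$windows[[w]]$cands
      if (!nrow(cands)) next
      cands <- featurize(cands, fprev = truth[w - 1L] / 60)
      cands <- label_candidates(cands, truth[w], cfg$label_tol_bpm)
      feats[[length(feats) + 1L]] <-
        data.frame(C = cands$C, S = cands$S, label = cands$label,
                   session = i, window = w)
    }
    if (!length(feats)) {
      warning("session ", i, " produced no candidates; skipped")
      next
    }
    out[[i]] <- do.call(rbind, feats)
  }
  pooled <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(pooled) || !nrow(pooled)) stop("corpus produced no candidates")
  rownames(pooled) <- NULL
  pooled
}
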