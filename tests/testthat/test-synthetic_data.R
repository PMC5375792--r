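test_that("simulation is bitwise deterministic given the seed", {
  a <- simulate_session(sim_config(duration_s = 20, seed = 5L))
  b <- simulate_session(sim_config(duration_s = 20, seed = 5L))
  expect_identical(a$ppg, b$ppg)
  expect_identical(a$accel, b$accel)
  expect_identical(a$truth_bpm, b$truth_bpm)
  c_ <- simulate_session(sim_config(duration_s = 20, seed = 6L))
  expect_false(identical(a$ppg, c_$ppg))
})

test_that("the default treadmill protocol stays inside 60-180 BPM", {
  rec <- simulate_session(sim_config(seed = 2L))
  expect_gte(min(rec$truth_bpm), 60)
  expect_lte(max(rec$truth_bpm), 180)
  # windows cover the session under the 8 s / 2 s convention at 25 Hz
  expect_equal(length(rec$truth_bpm),
               nrow(plan_windows(ncol(rec$ppg) %/% 5, default_config())$slices))
})

test_that("protocols outside physiologic bounds are rejected", {
  expect_error(sim_config(hr_protocol = list(c(60, 100, 260))), "physiologic")
  expect_error(sim_config(hr_protocol = list(c(60, 30, 100))), "physiologic")
})

test_that("a clean window's dominant spectral bin sits at the cardiac frequency", {
  cfg <- default_config()
  scfg <- sim_config(duration_s = 24,
                     hr_protocol = list(c(24, 120, 122)),
                     alpha = 0, ppg_noise_sd = 0, accel_noise_sd = 0.05,
                     seed = 8L)
  rec <- simulate_session(scfg, cfg)
  pre <- preprocess_record(rec, cfg)
  sl <- pre$plan$slices[2L, ]
  fr <- mfocuss(t(pre$ppg[, (sl[1L] + 1L):sl[2L]]),
                dft_dictionary(200L, cfg$N))
  peak_bin <- fold_bin(which.max(fr$row_norm) - 1L, cfg$N)
  truth_bin <- rec$truth_bpm[2L] / 60 * cfg$N / cfg$fs_target
  expect_lte(abs(peak_bin - truth_bin), 1)
})

test_that("PPG artifact and accelerometer share the same dominant frequency", {
  base <- sim_config(duration_s = 24, hr_protocol = list(c(24, 150, 152)),
                     alpha = 0, seed = 9L)
  with_art <- sim_config(duration_s = 24, hr_protocol = list(c(24, 150, 152)),
                         alpha = 2, seed = 9L)
  r0 <- simulate_session(base)
  r2 <- simulate_session(with_art)
  # identical seed: the PPG difference is exactly the coupled artifact
  artifact <- r2$ppg[1, ] - r0$ppg[1, ]
  win <- 1001:2000
  dom <- function(x) which.max(Mod(fft(x * signal::hanning(length(x))))[2:500])
  expect_lte(abs(dom(artifact[win]) - dom(r2$accel[1, win])), 1)
})

test_that("session files written by the generator round-trip with truth", {
  rec <- tiny_record(duration_s = 16, seed = 12L)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "sim.mat"); tf <- file.path(tmp, "sim_truth.txt")
  write_record(rec, f, truth_path = tf)
  back <- load_record(f, truth_path = tf)
  expect_equal(back$ppg, rec$ppg, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$truth_bpm, rec$truth_bpm, tolerance = 1e-9)
})

test_that("the training corpus carries both classes and labels cleanly", {
  corpus <- shared_corpus()
  expect_true(all(c("C", "S", "label") %in% names(corpus)))
  expect_gt(sum(corpus$label == 1L), 0)
  expect_gt(sum(corpus$label == 0L), 0)
  expect_true(all(corpus$C > 0 & corpus$C <= 1))
  expect_true(all(corpus$S >= 0))
  # at most one true label per window
  per_win <- tapply(corpus$label, paste(corpus$session, corpus$window),
                    sum)
  expect_true(all(per_win <= 1))
  expect_error(simulate_training_corpus(0L), "at least 1")
})

test_that("in a noise-free slow session the cardiac peak dominates the candidates", {
  # The adaptive filter at the working step size injects a small amount of
  # intermodulation energy even for perfectly coherent tones, so a handful of
  # windows see spurious high-frequency candidates outshine the cardiac bin;
  # the large majority must still be topped by the true peak, and the full
  # tracker must ride through the rest.
  cfg <- default_config()
  scfg <- sim_config(duration_s = 60, hr_protocol = list(c(60, 100, 106)),
                     alpha = 0, ppg_noise_sd = 0, accel_noise_sd = 0,
                     seed = 13L)
  rec <- simulate_session(scfg, cfg)
  aw <- analyze_windows(rec, cfg)
  top_true <- vapply(seq_along(aw$windows), function(w) {
    cands <- label_candidates(aw$windows[[w]]$cands, rec$truth_bpm[w],
                              cfg$label_tol_bpm)
    nrow(cands) > 0 && cands$label[which.max(cands$coe)] == 1L
  }, TRUE)
  expect_gte(mean(top_true), 0.7)
  trace <- estimate_session(rec, cfg, shared_model())
  expect_lte(aae(trace$bpm_est, trace$bpm_true), 1.47)
})
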