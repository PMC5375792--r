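test_that("candidate discovery applies the adaptive threshold to strict local maxima", {
  r <- find_candidates(c(0, 1, 2, 1, 0), xi = 0.7, fs = 25, N = 1024)
  expect_equal(r$bin, 2L)
  expect_equal(r$coe, 2)
  expect_equal(r$freq_hz, 2 * 25 / 1024)

  # kappa = 0.7 * max: a secondary peak below it is dropped
  r2 <- find_candidates(c(0, 1.3, 0, 0, 2, 0), xi = 0.7)
  expect_equal(r2$bin, 4L)

  # plateau: one candidate at the leftmost plateau bin
  r3 <- find_candidates(c(0, 2, 2, 0, 0), xi = 0.7)
  expect_equal(r3$bin, 1L)
  expect_equal(nrow(r3), 1L)

  # boundary bins compare against their single neighbor
  r4 <- find_candidates(c(3, 1, 0, 0, 2.5), xi = 0.7)
  expect_equal(r4$bin, c(0L, 4L))

  expect_equal(nrow(find_candidates(rep(0, 10))), 0L)
})

test_that("channel merging unions bins and keeps the larger coefficient", {
  a <- data.frame(bin = 30L, freq_hz = 30 * 25 / 1024, coe = 5, channel = 1L)
  b <- data.frame(bin = 40L, freq_hz = 40 * 25 / 1024, coe = 2, channel = 2L)
  expect_equal(merge_channels(a, b)$bin, c(30L, 40L))
  b2 <- transform(a, coe = 7, channel = 2L)
  m <- merge_channels(a, b2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$coe, 7)
  expect_equal(m$channel, 2L)
  empty <- a[0, ]
  expect_equal(merge_channels(empty, a)$bin, 30L)
  expect_equal(nrow(merge_channels(empty, empty)), 0L)
})

test_that("features are the coefficient ratio and the distance to the previous estimate", {
  cands <- data.frame(bin = c(60L, 70L), freq_hz = c(1.6, 1.7),
                      coe = c(5, 4), channel = 1L)
  f <- featurize(cands, fprev = 1.5)
  expect_equal(f$C, c(1, 0.8))
  expect_equal(f$S, c(0.1, 0.2))
  one <- featurize(cands[1, ], fprev = 1.6)
  expect_equal(one$C, 1)
  expect_error(featurize(cands, fprev = NA_real_), "not initialized")
})

test_that("training labels mark at most one candidate, closest to truth, ties to lower bin", {
  mk <- function(bpm, bin) data.frame(bin = bin, freq_hz = bpm / 60,
                                      coe = 1, channel = 1L)
  c1 <- mk(90, 61L)
  expect_equal(label_candidates(c1, 90.5, 2)$label, 1L)
  c2 <- rbind(mk(89, 60L), mk(91, 62L))
  expect_equal(label_candidates(c2, 90, 2)$label, c(1L, 0L))  # tie -> lower bin
  c3 <- rbind(mk(70, 48L), mk(120, 82L))
  expect_equal(label_candidates(c3, 90, 2)$label, c(0L, 0L))
})

test_that("the SVM separates a linearly separable toy set and validates inputs", {
  with_seed(41, {
    true_f <- data.frame(C = runif(20, 0.8, 1), S = runif(20, 0, 0.05))
    false_f <- data.frame(C = runif(20, 0, 0.3), S = runif(20, 0.5, 1))
  })
  feats <- rbind(true_f, false_f)
  labels <- rep(c(1L, 0L), each = 20)
  clf <- train_classifier(feats, labels)
  expect_equal(mean(as.integer(classify_peaks(clf, feats)) == labels), 1)
  expect_error(train_classifier(true_f, rep(1L, 20)), "class")
})

test_that("classifier artifacts round-trip and refuse version mismatches", {
  clf <- shared_model()
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, tmp)
  back <- load_classifier(tmp)
  probe <- data.frame(C = c(1, 0.4, 0.9), S = c(0.02, 0.8, 0.3))
  expect_identical(classify_peaks(back, probe), classify_peaks(clf, probe))
  bad <- unclass(clf); bad$version <- 99L
  class(bad) <- "peak_classifier"
  tmp2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, tmp2)
  expect_error(load_classifier(tmp2), "version mismatch")
})

test_that("selection rules and the prediction mechanism follow the stated branches", {
  cfg <- default_config()
  mk_state <- function(fprev, history, predictpre) {
    st <- new_tracker_state(cfg)
    st$fprev <- fprev; st$history <- history
    st$predictpre <- predictpre; st$initialized <- TRUE
    st
  }
  cand <- function(freq, coe = 1, pred = TRUE) {
    data.frame(bin = as.integer(round(freq * 1024 / 25)), freq_hz = freq,
               coe = coe, channel = 1L, C = 1, S = 0, pred = pred)
  }

  # rule 2: several predicted-true -> closest to fprev
  st <- mk_state(1.45, seq(1.36, 1.45, by = 0.01), 1.45)
  sel <- select_peak(rbind(cand(1.4), cand(1.6)), st)
  expect_equal(sel$f_hr, 1.4)
  expect_equal(sel$flag, "rule2")

  # rule 1: exactly one predicted-true
  st <- mk_state(1.45, seq(1.36, 1.45, by = 0.01), 1.45)
  sel1 <- select_peak(rbind(cand(1.4, pred = FALSE), cand(1.5)), st)
  expect_equal(sel1$f_hr, 1.5)
  expect_equal(sel1$flag, "rule1")

  # rule 3, rising trend: fprev + 0.02
  st <- mk_state(1.50, seq(1.41, 1.50, by = 0.01), 1.50)
  sel2 <- select_peak(cand(1.9, pred = FALSE), st)
  expect_equal(sel2$f_hr, 1.52)
  expect_equal(sel2$flag, "predicted")

  # rule 3, flat trend: hold
  st <- mk_state(1.50, rep(1.5, 10), 1.5)
  sel3 <- select_peak(cand(1.9, pred = FALSE), st)
  expect_equal(sel3$f_hr, 1.50)

  # rule 3, falling trend: fprev - 0.02
  st <- mk_state(1.50, seq(1.59, 1.50, by = -0.01), 1.50)
  sel4 <- select_peak(cand(1.9, pred = FALSE), st)
  expect_equal(sel4$f_hr, 1.48)

  # no candidates at all also takes the prediction branch
  st <- mk_state(1.50, rep(1.5, 10), 1.5)
  sel5 <- select_peak(cand(1.5)[0, ], st)
  expect_equal(sel5$f_hr, 1.50)
  expect_equal(sel5$flag, "predicted")
})

test_that("the first window initializes from the in-band maximum", {
  cfg <- default_config()
  st <- new_tracker_state(cfg)
  cands <- data.frame(bin = c(10L, 61L, 180L),
                      freq_hz = c(10, 61, 180) * 25 / 1024,
                      coe = c(9, 5, 7), channel = 1L)
  # bins 10 (0.24 Hz) and 180 (4.39 Hz) are outside 0.5-3 Hz
  sel <- select_peak(cands, st)
  expect_equal(sel$f_hr, 61 * 25 / 1024)
  expect_equal(sel$flag, "initialized")
  expect_true(sel$state$initialized)
  expect_error(select_peak(cands[0, ], new_tracker_state(cfg)),
               "initialization failed")
})

test_that("the smoother extrapolates a perfect line and falls back to the mean", {
  h <- 1.5 + 0.01 * (0:9)
  expect_equal(smoother_predict(h), 1.5 + 0.01 * 10, tolerance = 1e-10)
  expect_equal(smoother_predict(rep(1.5, 10)), 1.5)
  expect_equal(smoother_predict(1.5), 1.5)
  expect_equal(smoother_predict(c(1.4, 1.6)), 1.5)
  expect_error(smoother_predict(numeric(0)), "empty history")
})

test_that("frequency-to-BPM conversion is exact", {
  expect_equal(to_bpm(1.5), 90)
  expect_equal(to_bpm(0), 0)
  expect_equal(to_bpm(25 / 1024), 25 * 60 / 1024)  # one grid bin ~ 1.4648 BPM
  expect_error(to_bpm(-0.1), "nonnegative")
})

test_that("rule-3 estimates move by exactly one prediction step or not at all", {
  cfg <- default_config()
  st <- new_tracker_state(cfg)
  st$fprev <- 1.5; st$initialized <- TRUE
  st$history <- with_seed(42, 1.5 + cumsum(rnorm(10, sd = 0.01)))
  st$predictpre <- 1.49
  none <- data.frame(bin = integer(0), freq_hz = numeric(0),
                     coe = numeric(0), channel = integer(0))
  prev <- st$fprev
  for (i in 1:15) {
    sel <- select_peak(none, st)
    st <- sel$state
    expect_true(abs(abs(sel$f_hr - prev) - 0.02) < 1e-12 ||
                  abs(sel$f_hr - prev) < 1e-12)
    prev <- sel$f_hr
  }
})
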