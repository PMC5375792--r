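# Spectral peak tracking: candidate discovery on the cleansed spectra, the
# two-feature description of each candidate (coefficient ratio and distance
# to the previous estimate), SVM true/false-peak classification, the three
# selection rules, and the trend-extrapolation prediction fallback.

CLASSIFIER_VERSION <- 1L

#' Discover candidate spectral peaks
#'
#' A bin is a candidate when it is a strict local maximum (greater than both
#' neighbors; boundary bins compare to their single neighbor) whose
#' coefficient exceeds the adaptive threshold `kappa = xi * max(s)`. Runs of
#' equal values that stand above both flanking values (plateaus) yield one
#' candidate at the leftmost plateau bin.
#'
#' @param s cleansed spectrum over bins `0..max_bin` (0-based).
#' @param xi threshold fraction (default 0.7).
#' @param fs analysis sampling rate, Hz.
#' @param N full grid size (bin `n` is `n * fs / N` Hz).
#' @param channel integer label recorded on each candidate.
#' @return data.frame with columns `bin` (0-based), `freq_hz`, `coe`,
#'   `channel`; zero rows for an all-zero spectrum.
#' @export
find_candidates <- function(s, xi = 0.7, fs = 25, N = 1024, channel = 1L) {
  empty <- data.frame(bin = integer(0), freq_hz = numeric(0),
                      coe = numeric(0), channel = integer(0))
  if (!length(s) || all(s == 0)) return(empty)
  kappa <- xi * max(s)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])       # value before each run (-Inf at edge)
  right <- c(r$values[-1L], -Inf)     # value after each run
  is_peak <- r$values > left & r$values > right & r$values > kappa
  bins <- starts[is_peak] - 1L        # leftmost bin of the run, 0-based
  data.frame(bin = bins, freq_hz = bins * fs / N,
             coe = r$values[is_peak],
             channel = rep(as.integer(channel), length(bins)))
}

#' Merge candidate lists from the two PPG channels
#'
#' Union by bin; when both channels propose the same bin the larger
#' coefficient is kept. The coefficient ratio feature is later computed over
#' this merged set.
#'
#' @param c1,c2 candidate data.frames from [find_candidates()].
#' @return merged candidate data.frame, ordered by bin.
#' @export
merge_channels <- function(c1, c2) {
  all <- rbind(c1, c2)
  if (!nrow(all)) return(all)
  all <- all[order(all$bin, -all$coe), , drop = FALSE]
  merged <- all[!duplicated(all$bin), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Compute candidate features
#'
#' Adds the coefficient ratio `C = coe / max(coe)` (over the merged set) and
#' the distance to the previous estimate `S = |freq_hz - fprev|` in Hz.
#'
#' @param cands merged candidate data.frame.
#' @param fprev previous accepted frequency, Hz.
#' @return the data.frame with columns `C` and `S` appended.
#' @export
featurize <- function(cands, fprev) {
  if (!nrow(cands)) {
    cands$C <- numeric(0); cands$S <- numeric(0)
    return(cands)
  }
  if (!is.finite(fprev)) stop("tracker state not initialized: fprev unknown")
  cands$C <- cands$coe / max(cands$coe)
  cands$S <- abs(cands$freq_hz - fprev)
  cands
}

#' Label candidates against ground truth (training only)
#'
#' The candidate closest to the true heart rate, and within
#' `label_tol_bpm`, is labeled the true peak (ties broken to the lower bin);
#' every other candidate is labeled false. At most one true label per window.
#'
#' @param cands candidate data.frame with `freq_hz` and `bin`.
#' @param true_bpm ground-truth heart rate for the window.
#' @param label_tol_bpm labeling tolerance in BPM (default 2).
#' @return the data.frame with an integer `label` column (1 true, 0 false).
#' @export
label_candidates <- function(cands, true_bpm, label_tol_bpm = 2) {
  cands$label <- integer(nrow(cands))
  if (!nrow(cands)) return(cands)
  err <- abs(cands$freq_hz * 60 - true_bpm)
  ok <- which(err <= label_tol_bpm)
  if (length(ok)) {
    best <- ok[order(err[ok], cands$bin[ok])][1L]
    cands$label[best] <- 1L
  }
  cands
}

#' Train the true-peak SVM classifier
#'
#' Fits a support vector machine (linear kernel by default) on min-max-scaled
#' `(C, S)` features, with class weights inversely proportional to class
#' frequency. Scaling parameters are fitted on the training features only and
#' stored with the model.
#'
#' @param features data.frame (or matrix) with columns `C` and `S`.
#' @param labels integer/logical labels (1 = true peak).
#' @param kernel SVM kernel spec (passed to [e1071::svm()]).
#' @param cost SVM cost parameter.
#' @return object of class `peak_classifier`.
#' @export
train_classifier <- function(features, labels, kernel = "linear", cost = 1) {
  features <- as.data.frame(features)[, c("C", "S")]
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) {
    stop("training set has no '", names(tab)[tab == 0L][1L],
         "' class; both true and false peaks are required")
  }
  lo <- vapply(features, min, 0); hi <- vapply(features, max, 0)
  rng <- pmax(hi - lo, .Machine$double.eps)
  scaled <- sweep(sweep(as.matrix(features), 2L, lo), 2L, rng, "/")
  y <- factor(labels, levels = c(0L, 1L))
  wts <- as.numeric(sum(tab) / (2 * tab)); names(wts) <- names(tab)
  fit <- e1071::svm(scaled, y, kernel = kernel, cost = cost,
                    scale = FALSE, class.weights = wts)
  structure(list(fit = fit, scale_min = lo, scale_range = rng,
                 kernel = kernel, cost = cost,
                 n_train = length(labels), class_counts = as.integer(tab),
                 version = CLASSIFIER_VERSION),
            class = "peak_classifier")
}

#' @export
print.peak_classifier <- function(x, ...) {
  cat(sprintf(
    "<peak_classifier> %s-kernel SVM on (C, S); trained on %d peaks (%d false / %d true)\n",
    x$kernel, x$n_train, x$class_counts[1L], x$class_counts[2L]))
  invisible(x)
}

#' Classify candidates as true or false peaks
#'
#' @param clf a [train_classifier()] model.
#' @param cands candidate data.frame with `C` and `S` columns.
#' @param decision when TRUE also return the SVM decision values.
#' @return logical vector (TRUE = predicted true peak), with attribute
#'   `decision` when requested.
#' @export
classify_peaks <- function(clf, cands, decision = FALSE) {
  stopifnot(inherits(clf, "peak_classifier"))
  if (!nrow(cands)) return(logical(0))
  m <- as.matrix(cands[, c("C", "S")])
  scaled <- sweep(sweep(m, 2L, clf$scale_min), 2L, clf$scale_range, "/")
  pr <- predict(clf$fit, scaled, decision.values = decision)
  out <- pr == "1"
  if (decision) attr(out, "decision") <- attr(pr, "decision.values")
  out
}

#' Persist / restore a trained peak classifier
#'
#' The artifact carries a format version; loading refuses a mismatched
#' version rather than silently reinterpreting it.
#'
#' @param clf a `peak_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "peak_classifier"))
  saveRDS(clf, path, version = 2)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "peak_classifier") ||
      !identical(clf$version, CLASSIFIER_VERSION)) {
    stop("classifier artifact version mismatch (expected ",
         CLASSIFIER_VERSION, ")")
  }
  clf
}

#' Fresh tracker state
#'
#' @param cfg a [default_config()] list.
#' @return list of class `tracker_state`.
#' @export
new_tracker_state <- function(cfg = default_config()) {
  structure(list(fprev = NA_real_, history = numeric(0),
                 predictpre = NA_real_, initialized = FALSE,
                 smoother_window = cfg$smoother_window,
                 pred_step_hz = cfg$pred_step_hz,
                 init_band_hz = cfg$init_band_hz,
                 bpm_range = cfg$bpm_range),
            class = "tracker_state")
}

#' Trend prediction from the estimate history
#'
#' Ordinary least-squares line through the last (up to 10) accepted
#' frequencies, evaluated one step ahead; with fewer than 3 points the mean
#' of the history is returned.
#'
#' @param history numeric vector of recent frequency estimates, Hz (oldest
#'   first).
#' @return predicted next frequency, Hz.
#' @export
smoother_predict <- function(history) {
  n <- length(history)
  if (n == 0L) stop("empty history: smoother called before initialization")
  if (n < 3L) return(mean(history))
  idx <- seq_len(n)
  fit <- lm.fit(cbind(1, idx), history)
  sum(coef(fit) * c(1, n + 1))
}

#' Select the heart-rate peak for one window
#'
#' Applies the selection rules to classifier-labeled candidates:
#' exactly one predicted-true peak is taken as is (rule 1); among several,
#' the one closest to the previous estimate wins, ties to the lower
#' frequency (rule 2); with none, the prediction mechanism nudges the
#' previous estimate by `pred_step_hz` in the direction of the smoother
#' trend `h = predict - predictpre` (rule 3). On the first window the state
#' is initialized from the largest-coefficient candidate inside the adult
#' heart-rate band.
#'
#' @param cands candidate data.frame; for initialized states it must carry
#'   `C`, `S` and a logical `pred` column (classifier output).
#' @param state a [new_tracker_state()] (possibly updated).
#' @return list: `f_hr` (Hz), `state` (updated), `flag` (one of
#'   `"initialized"`, `"rule1"`, `"rule2"`, `"predicted"`).
#' @export
select_peak <- function(cands, state) {
  stopifnot(inherits(state, "tracker_state"))
  if (!state$initialized) {
    if (!nrow(cands)) {
      stop("initialization failed: no spectral candidates in the first window")
    }
    band <- state$init_band_hz
    in_band <- cands[cands$freq_hz >= band[1L] & cands$freq_hz <= band[2L], ,
                     drop = FALSE]
    pick <- if (nrow(in_band)) in_band else cands
    f_hr <- pick$freq_hz[which.max(pick$coe)]
    state$fprev <- f_hr
    state$history <- f_hr
    state$initialized <- TRUE
    return(list(f_hr = f_hr, state = state, flag = "initialized"))
  }
  pred_now <- smoother_predict(state$history)
  h <- if (is.finite(state$predictpre)) pred_now - state$predictpre else 0
  if (abs(h) < 1e-9) h <- 0   # numeric zero-band so a flat trend holds
  true_set <- if (nrow(cands)) cands[which(cands$pred), , drop = FALSE]
              else cands
  if (!is.null(true_set) && nrow(true_set) == 1L) {
    f_hr <- true_set$freq_hz
    flag <- "rule1"
  } else if (!is.null(true_set) && nrow(true_set) > 1L) {
    d <- abs(true_set$freq_hz - state$fprev)
    best <- order(d, true_set$freq_hz)[1L]
    f_hr <- true_set$freq_hz[best]
    flag <- "rule2"
  } else {
    f_hr <- state$fprev + state$pred_step_hz * sign(h)
    flag <- "predicted"
  }
  lim <- state$bpm_range / 60
  if (f_hr < lim[1L] || f_hr > lim[2L]) {
    warning("estimate ", round(f_hr * 60, 1), " BPM outside ",
            state$bpm_range[1L], "-", state$bpm_range[2L],
            " BPM; clamped")
    f_hr <- min(max(f_hr, lim[1L]), lim[2L])
  }
  state$predictpre <- pred_now
  state$fprev <- f_hr
  state$history <- tail(c(state$history, f_hr), state$smoother_window)
  list(f_hr = f_hr, state = state, flag = flag)
}

#' Convert a frequency estimate to beats per minute
#'
#' @param f_hr frequency in Hz (nonnegative).
#' @return heart rate in BPM (`f_hr * 60`).
#' @export
to_bpm <- function(f_hr) {
  if (any(f_hr < 0)) stop("frequency must be nonnegative")
  f_hr * 60
}
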