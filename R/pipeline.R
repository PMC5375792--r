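# Session orchestration: preprocessing, per-window motion reference and LMS
# (with weights carried across windows of a session), joint sparse spectra,
# spectrum subtraction, candidate discovery, SVM-guided peak selection.

#' Per-window spectral analysis of a session
#'
#' Runs every stage up to (and including) candidate discovery: preprocess,
#' per-window PCA motion reference, streaming LMS on both PPG channels (tap
#' weights are continuous across the session; each sample is filtered once,
#' using the reference of the first window that covers it... see Details),
#' Regularized M-FOCUSS spectra of the cleansed PPG pair and of the
#' acceleration triplet on the same grid, energy normalization, envelope
#' subtraction with the relative floor, and per-channel candidate discovery.
#'
#' @details The LMS recursion is continuous: windows overlap by 6 s, so each
#' new window contributes only its last 2 s of fresh samples to the stream;
#' those samples are filtered with the current window's PCA reference
#' (sliced to the fresh segment) starting from the weights left by the
#' previous window. Windows are then cut from the cleansed stream.
#'
#' @param record a [sensor_record()].
#' @param cfg a [default_config()].
#' @return list: `plan` (the [plan_windows()] result), `windows` (per window:
#'   `cands` merged candidate data.frame, `clean` the
#'   [cleanse_window_spectra()] output, `pca` the [first_pc_reference()]
#'   summary), `cleansed` (2 x T' LMS output stream).
#' @export
analyze_windows <- function(record, cfg = default_config()) {
  pre <- preprocess_record(record, cfg)
  plan <- pre$plan
  n_win <- nrow(plan$slices)
  win_len <- plan$slices[1L, "end"] - plan$slices[1L, "start"]
  dict <- dft_dictionary(win_len, cfg$N)
  cleansed <- matrix(0, 2L, ncol(pre$ppg))
  lms_states <- list(NULL, NULL)
  windows <- vector("list", n_win)
  done <- 0L  # samples already filtered
  for (w in seq_len(n_win)) {
    s0 <- plan$slices[w, "start"]; e0 <- plan$slices[w, "end"]
    acc_win <- pre$accel[, (s0 + 1L):e0, drop = FALSE]
    pca <- first_pc_reference(acc_win)
    fresh <- (done + 1L):e0
    ref_fresh <- pca$scores[(length(pca$scores) - length(fresh) + 1L):
                              length(pca$scores)]
    for (h in 1:2) {
      st <- lms_denoise(pre$ppg[h, fresh], ref_fresh,
                        order = cfg$lms_order, mu = cfg$mu,
                        state = lms_states[[h]])
      cleansed[h, fresh] <- st$cleansed
      lms_states[[h]] <- st
    }
    done <- e0
    idx <- (s0 + 1L):e0
    stage <- "sparse spectrum"
    res <- tryCatch({
      fr_ppg <- mfocuss(t(cleansed[, idx, drop = FALSE]), dict,
                        lam = cfg$lam, p = cfg$p, max_iter = cfg$mf_max_iter,
                        tol = cfg$mf_tol, prune = cfg$mf_prune)
      fr_acc <- mfocuss(t(pre$accel[, idx, drop = FALSE]), dict,
                        lam = cfg$lam, p = cfg$p, max_iter = cfg$mf_max_iter,
                        tol = cfg$mf_tol, prune = cfg$mf_prune)
      stage <- "spectrum subtraction"
      clean <- cleanse_window_spectra(fr_ppg$S, fr_acc$S, cfg)
      stage <- "candidate discovery"
      c1 <- find_candidates(clean$s1$s, cfg$xi, cfg$fs_target, cfg$N,
                            channel = 1L)
      c2 <- find_candidates(clean$s2$s, cfg$xi, cfg$fs_target, cfg$N,
                            channel = 2L)
      list(cands = merge_channels(c1, c2), clean = clean,
           pca = pca[c("eigenvalues", "explained_ratio", "degenerate")])
    }, error = function(e) {
      stop("window ", w, " failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    windows[[w]] <- res
  }
  list(plan = plan, windows = windows, cleansed = cleansed)
}

#' Estimate the heart-rate trace of one session
#'
#' Full pipeline: [analyze_windows()], then per window the candidate features
#' against the previous estimate, SVM classification, and the selection
#' rules with the prediction fallback. The first window initializes the
#' tracker from the largest candidate inside the adult heart-rate band.
#'
#' @param record a [sensor_record()] (with or without ground truth).
#' @param cfg a [default_config()].
#' @param model a trained [train_classifier()] peak classifier.
#' @return data.frame of class `hr_trace`: `window_index`, `window_start_s`,
#'   `bpm_est`, `bpm_true` (NA without ground truth), `flag`.
#' @export
estimate_session <- function(record, cfg = default_config(), model) {
  stopifnot(inherits(model, "peak_classifier"))
  aw <- analyze_windows(record, cfg)
  n_win <- length(aw$windows)
  state <- new_tracker_state(cfg)
  bpm <- numeric(n_win)
  flags <- character(n_win)
  for (w in seq_len(n_win)) {
    cands <- aw$windows[[w]]$cands
    if (state$initialized && nrow(cands)) {
      cands <- featurize(cands, state$fprev)
      cands$pred <- classify_peaks(model, cands)
    }
    sel <- select_peak(cands, state)
    state <- sel$state
    bpm[w] <- to_bpm(sel$f_hr)
    flags[w] <- sel$flag
  }
  truth <- record$truth_bpm
  if (!is.null(truth) && length(truth) != n_win) {
    stop("ground truth has ", length(truth), " values but the session has ",
         n_win, " analysis windows")
  }
  out <- data.frame(
    window_index = seq_len(n_win),
    window_start_s = aw$plan$slices[, "start"] / cfg$fs_target,
    bpm_est = bpm,
    bpm_true = if (is.null(truth)) NA_real_ else truth,
    flag = flags
  )
  class(out) <- c("hr_trace", "data.frame")
  out
}

#' @export
print.hr_trace <- function(x, ...) {
  cat(sprintf("<hr_trace> %d windows, %.1f-%.1f BPM; flags: %s\n",
              nrow(x), min(x$bpm_est), max(x$bpm_est),
              paste(names(table(x$flag)), table(x$flag), sep = "=",
                    collapse = ", ")))
  NextMethod()
}

#' Train the peak classifier on sessions with ground truth
#'
#' Pools labeled candidate features across the given records (teacher-forced
#' on ground truth, as in [simulate_training_corpus()]), trains the SVM, and
#' reports stratified 10-fold cross-validated accuracy.
#'
#' @param records list of [sensor_record()]s, each with `truth_bpm`.
#' @param cfg a [default_config()].
#' @param cv_folds folds for the accuracy report (default 10; set to 0 to
#'   skip).
#' @return a `peak_classifier` with attributes `cv_accuracy` (percent) and
#'   `n_features`.
#' @export
run_training <- function(records, cfg = default_config(), cv_folds = 10L) {
  if (!length(records)) stop("no training sessions given")
  missing_truth <- which(vapply(records, function(r) is.null(r$truth_bpm),
                                TRUE))
  if (length(missing_truth)) {
    stop("sessions without ground truth: ",
         paste(missing_truth, collapse = ", "))
  }
  feats <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    aw <- analyze_windows(rec, cfg)
    truth <- rec$truth_bpm
    for (w in seq_along(aw$windows)[-1L]) {
      cands <- aw$windows[[w]]$cands
      if (!nrow(cands)) next
      cands <- featurize(cands, fprev = truth[w - 1L] / 60)
      cands <- label_candidates(cands, truth[w], cfg$label_tol_bpm)
      feats[[length(feats) + 1L]] <- cands[, c("C", "S", "label")]
    }
  }
  pool <- do.call(rbind, feats)
  if (is.null(pool) || !nrow(pool)) stop("training produced no candidates")
  clf <- train_classifier(pool[, c("C", "S")], pool$label,
                          kernel = cfg$svm_kernel)
  if (cv_folds >= 2L) {
    attr(clf, "cv_accuracy") <-
      as.numeric(cross_validate(pool[, c("C", "S")], pool$label,
                                k = cv_folds, seed = cfg$seed,
                                kernel = cfg$svm_kernel))
  }
  attr(clf, "n_features") <- nrow(pool)
  clf
}

#' Read / write a heart-rate trace CSV
#'
#' Columns: `window_index`, `window_start_s`, `bpm_est`, `bpm_true`, `flag`.
#'
#' @param trace an `hr_trace` data.frame.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- read.csv(path)
  class(out) <- c("hr_trace", "data.frame")
  out
}
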