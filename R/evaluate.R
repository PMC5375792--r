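# Agreement metrics between estimated and ground-truth heart-rate traces,
# and cross-validated accuracy of the peak classifier.

#' Average absolute error (BPM)
#'
#' `AAE = mean(|est - truth|)` over the analysis windows.
#'
#' @param est,truth equal-length BPM traces.
#' @return AAE in BPM.
#' @export
aae <- function(est, truth) {
  if (length(est) != length(truth)) stop("traces differ in length")
  if (!length(est)) stop("empty traces")
  mean(abs(est - truth))
}

#' Average absolute error percentage
#'
#' `AAEP = mean(|est - truth| / truth)`, reported in percent.
#'
#' @param est,truth equal-length BPM traces; `truth` strictly positive.
#' @return AAEP in percent.
#' @export
aaep <- function(est, truth) {
  if (length(est) != length(truth)) stop("traces differ in length")
  if (any(truth <= 0)) stop("ground truth must be strictly positive")
  mean(abs(est - truth) / truth) * 100
}

#' Bland-Altman agreement
#'
#' Differences are `est - truth`; `u` is their mean, `sigma` the sample
#' (n-1) standard deviation, and the limits of agreement are
#' `u +/- 1.96 sigma`.
#'
#' @param est,truth equal-length BPM traces, at least 2 windows.
#' @return list with `u`, `sigma`, `loa` (lower, upper).
#' @export
bland_altman <- function(est, truth) {
  if (length(est) != length(truth)) stop("traces differ in length")
  if (length(est) < 2L) stop("Bland-Altman needs at least 2 windows")
  d <- est - truth
  u <- mean(d)
  sigma <- sd(d)
  list(u = u, sigma = sigma, loa = c(u - 1.96 * sigma, u + 1.96 * sigma))
}

#' Pearson correlation between estimates and ground truth
#'
#' @param est,truth equal-length non-constant traces.
#' @return sample Pearson correlation coefficient.
#' @export
pearson <- function(est, truth) {
  if (length(est) != length(truth)) stop("traces differ in length")
  if (sd(est) == 0 || sd(truth) == 0) {
    stop("correlation undefined for a constant trace")
  }
  cor(est, truth)
}

#' Stratified k-fold cross-validated classifier accuracy
#'
#' Splits each class into `k` folds (seeded), trains the peak classifier on
#' k-1 folds and scores held-out accuracy, and returns the mean over folds in
#' percent.
#'
#' @param features data.frame with `C` and `S` columns.
#' @param labels integer/logical labels (1 = true peak).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param kernel,cost passed to [train_classifier()].
#' @return mean held-out accuracy, percent; per-fold accuracies attached as
#'   attribute `folds`.
#' @export
cross_validate <- function(features, labels, k = 10L, seed = 1L,
                           kernel = "linear", cost = 1) {
  labels <- as.integer(labels)
  if (k < 2L) stop("k must be at least 2")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k)) {
    stop("class '", names(counts)[counts < k][1L], "' has fewer than k=", k,
         " members; cannot stratify")
  }
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_idx(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    clf <- train_classifier(features[tr, , drop = FALSE], labels[tr],
                            kernel = kernel, cost = cost)
    pred <- classify_peaks(clf, features[!tr, , drop = FALSE])
    mean(as.integer(pred) == labels[!tr])
  }, 0)
  structure(mean(acc) * 100, folds = acc * 100)
}

# Local RNG stream that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample_idx = function(n) with_state(function() sample.int(n)),
    norm = function(n, sd = 1) with_state(function() rnorm(n, sd = sd)),
    unif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max))
  )
}

#' Evaluate an estimated heart-rate trace
#'
#' Bundles [aae()], [aaep()], [bland_altman()] and [pearson()] into one
#' report.
#'
#' @param est,truth equal-length BPM traces.
#' @param cv_accuracy optional cross-validated classifier accuracy (percent)
#'   to carry along.
#' @return list of class `eval_report`.
#' @export
evaluate_trace <- function(est, truth, cv_accuracy = NULL) {
  ba <- bland_altman(est, truth)
  structure(list(aae = aae(est, truth), aaep = aaep(est, truth),
                 u = ba$u, sigma = ba$sigma, loa = ba$loa,
                 pearson_r = pearson(est, truth),
                 n_windows = length(est), cv_accuracy = cv_accuracy),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  windows        %d\n", x$n_windows))
  cat(sprintf("  AAE            %.3f BPM\n", x$aae))
  cat(sprintf("  AAEP           %.3f %%\n", x$aaep))
  cat(sprintf("  Bland-Altman   u=%.3f, sigma=%.3f, LOA=[%.3f, %.3f] BPM\n",
              x$u, x$sigma, x$loa[1L], x$loa[2L]))
  cat(sprintf("  Pearson r      %.4f\n", x$pearson_r))
  if (!is.null(x$cv_accuracy)) {
    cat(sprintf("  CV accuracy    %.1f %%\n", as.numeric(x$cv_accuracy)))
  }
  invisible(x)
}

#' Emit Bland-Altman and scatter agreement plots
#'
#' Writes `bland_altman.pdf` (per-window differences against means, with the
#' bias and 1.96-sigma limits) and `scatter.pdf` (estimates against ground
#' truth with the identity line) into `dir`. PDF is used so the output is
#' device-independent.
#'
#' @param est,truth equal-length BPM traces.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
plot_agreement <- function(est, truth, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ba <- bland_altman(est, truth)
  f1 <- file.path(dir, "bland_altman.pdf")
  grDevices::pdf(f1, width = 6, height = 5)
  plot((est + truth) / 2, est - truth, pch = 20,
       xlab = "Mean of estimate and truth (BPM)",
       ylab = "Estimate - truth (BPM)", main = "Bland-Altman agreement")
  abline(h = c(ba$u, ba$loa), lty = c(1, 2, 2), col = c("black", "red", "red"))
  grDevices::dev.off()
  f2 <- file.path(dir, "scatter.pdf")
  grDevices::pdf(f2, width = 5.5, height = 5.5)
  plot(truth, est, pch = 20, xlab = "Ground-truth HR (BPM)",
       ylab = "Estimated HR (BPM)", main = "Estimate vs ground truth")
  abline(0, 1, col = "grey50")
  grDevices::dev.off()
  invisible(c(f1, f2))
}

#' Write an evaluation report as flat key-value JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  lines <- c(
    sprintf("aae_bpm: %.6f", report$aae),
    sprintf("aaep_percent: %.6f", report$aaep),
    sprintf("bland_altman_u_bpm: %.6f", report$u),
    sprintf("bland_altman_sigma_bpm: %.6f", report$sigma),
    sprintf("loa_lower_bpm: %.6f", report$loa[1L]),
    sprintf("loa_upper_bpm: %.6f", report$loa[2L]),
    sprintf("pearson_r: %.6f", report$pearson_r),
    sprintf("n_windows: %d", report$n_windows)
  )
  if (!is.null(report$cv_accuracy)) {
    lines <- c(lines, sprintf("cv_accuracy_percent: %.6f",
                              as.numeric(report$cv_accuracy)))
  }
  writeLines(lines, path)
  invisible(path)
}
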