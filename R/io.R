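#' Construct a sensor record
#'
#' A `sensor_record` holds one session: two PPG channels, three acceleration
#' channels, the sampling rate, and (optionally) per-window ground-truth heart
#' rate in BPM. All channels must be equal length and free of NaN/Inf.
#'
#' @param ppg 2 x T numeric matrix of PPG channels (arbitrary units).
#' @param accel 3 x T numeric matrix of acceleration channels.
#' @param fs sampling rate in Hz.
#' @param truth_bpm optional numeric vector, one ground-truth BPM per analysis
#'   window under the configured windowing.
#' @param subject_id text label.
#' @return An object of class `sensor_record`.
#' @export
sensor_record <- function(ppg, accel, fs, truth_bpm = NULL,
                          subject_id = "unknown") {
  ppg <- as.matrix(ppg); accel <- as.matrix(accel)
  if (nrow(ppg) != 2L) stop("ppg must have exactly 2 channels (rows)")
  if (nrow(accel) != 3L) stop("accel must have exactly 3 channels (rows)")
  if (ncol(ppg) != ncol(accel)) stop("ppg and accel lengths differ")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar")
  }
  check_finite(ppg, "ppg")
  check_finite(accel, "accel")
  if (!is.null(truth_bpm)) {
    truth_bpm <- as.numeric(truth_bpm)
    check_finite(truth_bpm, "truth_bpm")
  }
  structure(list(ppg = ppg, accel = accel, fs = fs, truth_bpm = truth_bpm,
                 subject_id = subject_id),
            class = "sensor_record")
}

check_finite <- function(x, what) {
  bad <- which(!is.finite(x))
  if (length(bad)) {
    if (is.matrix(x)) {
      smp <- (bad[1L] - 1L) %/% nrow(x) + 1L
      ch <- (bad[1L] - 1L) %% nrow(x) + 1L
      stop("non-finite value in ", what, " at sample ", smp, " (channel ",
           ch, ")", call. = FALSE)
    }
    stop("non-finite value in ", what, " at index ", bad[1L], call. = FALSE)
  }
  invisible(x)
}

#' @export
print.sensor_record <- function(x, ...) {
  cat(sprintf("<sensor_record> subject=%s  T=%d samples @ %g Hz (%.1f s)\n",
              x$subject_id, ncol(x$ppg), x$fs, ncol(x$ppg) / x$fs))
  cat(sprintf("  channels: 2 PPG + 3 accel; ground truth: %s\n",
              if (is.null(x$truth_bpm)) "absent"
              else sprintf("%d windows", length(x$truth_bpm))))
  invisible(x)
}

#' Load a recording session
#'
#' Reads a session from either the MATLAB-matrix dialect (one 6 x T double
#' matrix at 125 Hz, row order ECG, PPG1, PPG2, ACCX, ACCY, ACCZ; the ECG row
#' is discarded since ground truth is consumed from a companion file) or a
#' plain CSV dialect (header `ppg1,ppg2,accx,accy,accz` with optional `ecg`
#' column and a `# fs=125` comment line).
#'
#' @param path recording file.
#' @param format `"mat"` or `"csv"`; guessed from the extension by default.
#' @param truth_path optional companion file with one ground-truth BPM per
#'   analysis window; `.mat` (first variable, vector) or plain text/CSV
#'   (one value per line).
#' @param fs sampling rate assumed for `.mat` input (the distribution rate).
#' @param subject_id text label; defaults to the file stem.
#' @return A [sensor_record()].
#' @export
load_record <- function(path, format = c("auto", "mat", "csv"),
                        truth_path = NULL, fs = 125,
                        subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "csv"
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "mat") {
    vars <- read_mat(path)
    mats <- Filter(function(v) is.matrix(v) && nrow(v) == 6L, vars)
    if (!length(mats)) {
      rows <- vapply(vars, function(v) if (is.matrix(v)) nrow(v) else -1L, 0L)
      stop("expected a 6-row matrix (ECG, PPG1, PPG2, ACCX, ACCY, ACCZ); ",
           "found row counts: ", paste(rows, collapse = ", "))
    }
    m <- mats[[1L]]
    ppg <- m[2:3, , drop = FALSE]
    accel <- m[4:6, , drop = FALSE]
  } else {
    lines1 <- readLines(path, n = 5L)
    fs_line <- grep("^#\\s*fs\\s*=", lines1, value = TRUE)
    if (length(fs_line)) {
      fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[1L]))
    }
    df <- read.csv(path, comment.char = "#")
    need <- c("ppg1", "ppg2", "accx", "accy", "accz")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("CSV is missing channel columns: ",
           paste(missing_cols, collapse = ", "))
    }
    ppg <- t(as.matrix(df[, c("ppg1", "ppg2")]))
    accel <- t(as.matrix(df[, c("accx", "accy", "accz")]))
  }
  truth <- if (!is.null(truth_path)) load_truth(truth_path) else NULL
  sensor_record(ppg, accel, fs, truth_bpm = truth, subject_id = subject_id)
}

#' @rdname load_record
#' @export
load_truth <- function(truth_path) {
  if (!file.exists(truth_path)) stop("truth file not found: ", truth_path)
  if (grepl("\\.mat$", truth_path, ignore.case = TRUE)) {
    vars <- read_mat(truth_path)
    as.numeric(vars[[1L]])
  } else {
    as.numeric(read.csv(truth_path, header = FALSE, comment.char = "#")[[1L]])
  }
}

#' Write a recording session to disk
#'
#' Emits the same dialects [load_record()] reads: a `.mat` file with a 6 x T
#' matrix (a zero ECG placeholder row on top) or a CSV with a `# fs=` comment,
#' plus an optional companion per-window ground-truth file.
#'
#' @param record a [sensor_record()].
#' @param path output file; extension selects the dialect.
#' @param truth_path optional output path for the ground-truth vector
#'   (`.mat` or text, one BPM per line).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, truth_path = NULL) {
  stopifnot(inherits(record, "sensor_record"))
  if (grepl("\\.mat$", path, ignore.case = TRUE)) {
    m <- rbind(0, record$ppg, record$accel)
    write_mat(list(sig = m), path)
  } else {
    df <- data.frame(ppg1 = record$ppg[1L, ], ppg2 = record$ppg[2L, ],
                     accx = record$accel[1L, ], accy = record$accel[2L, ],
                     accz = record$accel[3L, ])
    con <- file(path, "w")
    writeLines(sprintf("# fs=%g", record$fs), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(truth_path)) {
    if (is.null(record$truth_bpm)) stop("record carries no ground truth")
    if (grepl("\\.mat$", truth_path, ignore.case = TRUE)) {
      write_mat(list(BPM0 = record$truth_bpm), truth_path)
    } else {
      writeLines(format(record$truth_bpm, digits = 12), truth_path)
    }
  }
  invisible(path)
}
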