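#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters for the heart-rate estimation
#' pipeline. Defaults follow the operating point used throughout the package:
#' 125 Hz recordings downsampled to 25 Hz, 8 s windows shifted by 2 s, a
#' 0.4--4 Hz second-order Butterworth band-pass, an order-25 LMS filter with
#' step size 0.005, a 1024-point redundant DFT grid solved by Regularized
#' M-FOCUSS (lambda = 1e-10), spectrum subtraction restricted to bins 0..199
#' with a 0.7 peak-discovery threshold and a 1/5 relative floor, and a
#' 0.02 Hz-per-window prediction step with a 10-value smoother history.
#'
#' @param ... named overrides of any default entry.
#' @return A list of class `ppghr_config`.
#' @export
#' @examples
#' cfg <- default_config(seed = 7)
#' cfg$mu
default_config <- function(...) {
  cfg <- list(
    fs_raw = 125,          # Hz, acquisition rate
    fs_target = 25,        # Hz, analysis rate after decimation
    window_s = 8,          # analysis window length, seconds
    shift_s = 2,           # window shift, seconds (6 s overlap)
    bp_low = 0.4,          # Hz, band-pass lower edge
    bp_high = 4,           # Hz, band-pass upper edge
    bp_order = 2,          # Butterworth order
    lms_order = 25,        # LMS tap count
    mu = 0.005,            # LMS step size
    tau = 1,               # row-sparsity weight (absorbed by lam, kept for record)
    lam = 1e-10,           # M-FOCUSS regularization
    p = 0.8,               # M-FOCUSS sparsity exponent, (0, 1]
    N = 1024,              # DFT grid size
    mf_max_iter = 100,
    mf_tol = 1e-4,         # relative Frobenius change stop rule
    mf_prune = 1e-4,       # row-norm pruning floor, relative to max row norm
    xi = 0.7,              # peak-discovery threshold fraction
    subtract_fraction = 0.2, # post-subtraction relative floor (pmax/5)
    max_bin = 199,         # analysis restricted to grid bins 0..max_bin
    pred_step_hz = 0.02,   # prediction-mechanism step, Hz per window
    smoother_window = 10,  # history length for the trend smoother
    smoother_legacy = 20,  # unused legacy smoother knob, recorded only
    label_tol_bpm = 2,     # training-label tolerance around ground truth
    init_band_hz = c(0.5, 3), # adult heart-rate band used for initialization
    bpm_range = c(30, 230),   # emitted-estimate clamp range
    svm_kernel = "linear",
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- "ppghr_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$fs_raw > 0, cfg$fs_target > 0,
    cfg$window_s > cfg$shift_s, cfg$shift_s > 0,
    cfg$bp_low > 0, cfg$bp_low < cfg$bp_high, cfg$bp_high < cfg$fs_target / 2,
    cfg$N > cfg$window_s * cfg$fs_target,
    cfg$xi > 0, cfg$xi < 1,
    cfg$p > 0, cfg$p <= 1,
    cfg$lam >= 0, cfg$mu > 0, cfg$lms_order >= 1,
    cfg$max_bin > 0, cfg$max_bin < cfg$N / 2
  )
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as a flat key-value YAML file mirroring
#' [default_config()].
#'
#' @param path file path.
#' @return `read_config()` returns a `ppghr_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' @rdname read_config
#' @param cfg a `ppghr_config` list.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.ppghr_config <- function(x, ...) {
  cat("<ppghr_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
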