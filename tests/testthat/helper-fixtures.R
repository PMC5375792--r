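# Shared fixtures, built once per test run and memoized: a labeled training
# corpus from synthetic sessions and the SVM peak classifier trained on it.

.fixtures <- new.env(parent = emptyenv())

shared_corpus <- function() {
  if (is.null(.fixtures$corpus)) {
    .fixtures$corpus <- simulate_training_corpus(
      5L, default_config(), seed = 100L, duration_s = 150)
  }
  .fixtures$corpus
}

shared_model <- function() {
  if (is.null(.fixtures$model)) {
    corpus <- shared_corpus()
    .fixtures$model <- train_classifier(corpus[, c("C", "S")], corpus$label)
  }
  .fixtures$model
}

# Memoized session estimates for the artifact-gain sweep (alpha -> hr_trace),
# shared between the end-to-end tests.
shared_sweep_trace <- function(alpha, seed = 42L, duration_s = 300) {
  key <- sprintf("trace_a%s_s%d_d%s", alpha, seed, duration_s)
  if (is.null(.fixtures[[key]])) {
    cfg <- default_config()
    rec <- simulate_session(
      sim_config(duration_s = duration_s, alpha = alpha, seed = seed), cfg)
    .fixtures[[key]] <- suppressWarnings(
      estimate_session(rec, cfg, shared_model()))
  }
  .fixtures[[key]]
}

# Deterministic local RNG helper for property loops.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# A small synthetic record for I/O and pipeline unit tests: near-constant
# heart rate so short sessions stay easy to track.
tiny_record <- function(duration_s = 40, alpha = 0.5, seed = 7L,
                        hr = c(100, 108)) {
  simulate_session(
    sim_config(duration_s = duration_s,
               hr_protocol = list(c(duration_s, hr[1L], hr[2L])),
               alpha = alpha, seed = seed),
    default_config())
}

# Conjugate-symmetric row-sparse ground truth on the redundant DFT grid:
# n_pairs active bins below Nyquist plus their mirrors, so Re(Phi X) = Phi X.
make_mmv_truth <- function(dict, bins, H = 2L, seed = 1L) {
  with_seed(seed, {
    X <- matrix(0i, dict$N, H)
    for (b in bins) {
      z <- complex(real = rnorm(H), imaginary = rnorm(H))
      z <- z / Mod(z) * runif(H, 0.5, 1.5)
      X[b + 1L, ] <- z
      X[dict$N - b + 1L, ] <- Conj(z)
    }
    X
  })
}

frob_err <- function(X, Xstar) {
  sqrt(sum(Mod(X - Xstar)^2)) / sqrt(sum(Mod(Xstar)^2))
}

# Brute-force single-support oracle: the bin whose single dictionary column
# (plus conjugate mirror) best explains Y in least squares.
brute_force_bin <- function(Y, dict) {
  half <- seq_len(dict$N %/% 2 - 1L)   # bins 1 .. N/2-1
  resid <- vapply(half, function(b) {
    A <- cbind(dict$Phi[, b + 1L], dict$Phi[, dict$N - b + 1L])
    fit <- qr.solve(A, Y + 0i)
    sum(Mod(Y - A %*% fit)^2)
  }, 0)
  half[which.min(resid)]
}
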