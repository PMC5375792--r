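# Joint sparse spectrum estimation on a redundant DFT dictionary with the
# Regularized M-FOCUSS iteration (iteratively reweighted minimum-norm steps
# promoting row sparsity across the measurement channels).

.dict_cache <- new.env(parent = emptyenv())

#' Redundant DFT dictionary
#'
#' Builds the M x N complex matrix `Phi[m, n] = exp(1i * 2*pi * m * n / N)`
#' (0-based indices). With `N > M` the frequency grid is finer than the FFT's:
#' column `n` corresponds to `n * fs / N` Hz. Dictionaries are cached per
#' `(M, N)`.
#'
#' @param M number of time samples (rows).
#' @param N grid size (columns); must exceed `M`.
#' @return list of class `dft_dictionary`: `Phi` (M x N complex), `M`, `N`.
#' @export
dft_dictionary <- function(M, N) {
  if (!(M > 0 && N > M)) {
    stop("dictionary must be redundant: need 0 < M < N, got M=", M,
         ", N=", N)
  }
  key <- paste0(M, "x", N)
  if (!is.null(.dict_cache[[key]])) return(.dict_cache[[key]])
  Phi <- exp(1i * 2 * pi * outer(0:(M - 1L), 0:(N - 1L)) / N)
  # column Gram lags: t[d+1] = sum_m exp(-2i pi m d / N) = (Phi^H Phi)[n, n+d]
  gram_lags <- fft(c(rep(1 + 0i, M), rep(0i, N - M)))
  lag_idx_M <- (outer(0:(M - 1L), 0:(M - 1L), "-") %% N) + 1L
  d <- structure(list(Phi = Phi, PhiH = Conj(t(Phi)), gram_lags = gram_lags,
                      lag_idx_M = lag_idx_M,
                      M = as.integer(M), N = as.integer(N)),
                 class = "dft_dictionary")
  .dict_cache[[key]] <- d
  d
}

#' @export
print.dft_dictionary <- function(x, ...) {
  cat(sprintf("<dft_dictionary> %d x %d complex exponentials\n", x$M, x$N))
  invisible(x)
}

#' Regularized M-FOCUSS joint sparse recovery
#'
#' Solves the multiple-measurement-vector problem `Y = Phi X + V` for a
#' row-sparse `X` by iteratively reweighted regularized minimum-norm steps:
#' with row norms `c[i] = ||X_k[i, ]||_2`, form `W = diag(c[i]^(1 - p/2))`,
#' `A = Phi W`, `Q = A^H (A A^H + lam I)^{-1} Y`, `X_{k+1} = W Q`, until the
#' relative Frobenius change drops below `tol` or `max_iter` is reached.
#' Rows with norm below `prune * max(c)` are pruned (removed from the active
#' set and zeroed), which is what makes the reweighting converge onto a
#' sparse support. Initialization is the matched filter `X_0 = Phi^H Y`.
#'
#' @param Y M x H real (or complex) measurement matrix; H columns share one
#'   row-sparse support (H = 2 for the PPG pair, H = 3 for acceleration).
#' @param dict a [dft_dictionary()] with matching `M`.
#' @param lam regularization added to the normal-equation kernel (1e-10).
#' @param p sparsity exponent in (0, 1]; smaller is sparser (default 0.8).
#' @param max_iter,tol stopping rule.
#' @param prune relative row-norm pruning floor.
#' @param track_objective when TRUE, records the regularized objective
#'   `||Y - Phi X||_F^2 + lam * sum(c[i]^p)` at each iterate.
#' @return list of class `spectral_frame`: `X` (N x H complex), `S` (N x H
#'   power spectrum, `|X|^2`), `row_norm` (length-N), `residual` (Frobenius
#'   norm of `Y - Re(Phi X)`), `iterations`, `converged`, and `objective`
#'   (when tracked).
#' @export
mfocuss <- function(Y, dict, lam = 1e-10, p = 0.8, max_iter = 100L,
                    tol = 1e-4, prune = 1e-4, track_objective = FALSE) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Mod(Y)))) stop("Y must be finite")
  if (nrow(Y) != dict$M) stop("Y has ", nrow(Y), " rows; dictionary expects ",
                              dict$M)
  N <- dict$N; H <- ncol(Y)
  if (all(Mod(Y) == 0)) {
    X <- matrix(0i, N, H)
    return(new_spectral_frame(X, Y, dict, iterations = 0L, converged = TRUE,
                              objective = if (track_objective) 0 else NULL))
  }
  Phi <- dict$Phi
  X <- Matrix_conj_crossprod(Phi, Y)        # matched-filter start, N x H
  active <- seq_len(N)
  obj <- if (track_objective) numeric(0) else NULL
  converged <- FALSE
  iterations <- 0L
  Dn_idx <- NULL
  last_active <- integer(0)
  for (k in seq_len(max_iter)) {
    iterations <- k
    Xa <- X[active, , drop = FALSE]
    cvec <- sqrt(rowSums(Mod(Xa)^2))
    keep <- cvec >= prune * max(cvec)
    if (!all(keep)) {
      active <- active[keep]
      Xa <- Xa[keep, , drop = FALSE]
      cvec <- cvec[keep]
    }
    w <- cvec^(1 - p / 2)
    # With A = Phi W, both normal-equation kernels are Toeplitz in the DFT
    # index difference, so they are assembled from precomputed lags instead
    # of dense Gram products.
    # A^H (A A^H + lam I)^{-1} Y == (A^H A + lam I)^{-1} A^H Y; pick the
    # smaller (better-conditioned) system.
    M_ <- nrow(Y)
    k_ <- length(active)
    Q <- if (k_ <= M_) {
      # G = W Phi_a^H Phi_a W via gram lags
      if (is.null(Dn_idx) || length(last_active) != k_ ||
          any(last_active != active)) {
        Dn_idx <- (outer(active - 1L, active - 1L, "-") %% dict$N) + 1L
        last_active <- active
      }
      G <- outer(w, w) * matrix(dict$gram_lags[Dn_idx], k_, k_)
      diag(G) <- Re(diag(G)) + lam
      B <- w * (dict$PhiH[active, , drop = FALSE] %*% (Y + 0i))
      solve_herm(G, B)
    } else {
      # K = Phi diag(w^2) Phi^H: K[m, m'] = sum_n w_n^2 e^{+2i pi (m-m') n/N}
      v <- complex(length.out = dict$N)
      v[active] <- w^2
      lagK <- Conj(fft(v))
      K <- matrix(lagK[dict$lag_idx_M], M_, M_)
      diag(K) <- Re(diag(K)) + lam
      Z <- solve_herm(K, Y + 0i)
      w * (dict$PhiH[active, , drop = FALSE] %*% Z)
    }
    Xnew_a <- Q * w
    Xnew <- matrix(0i, N, H)
    Xnew[active, ] <- Xnew_a
    delta <- frob(Xnew - X) / max(frob(X), .Machine$double.eps)
    X <- Xnew
    if (track_objective) {
      cn <- sqrt(rowSums(Mod(X)^2))
      obj <- c(obj, frob(Y - Phi %*% X)^2 + lam * sum(cn^p))
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  new_spectral_frame(X, Y, dict, iterations = iterations,
                     converged = converged, objective = obj)
}

# Hermitian positive-definite solve with escalating diagonal jitter as a
# last-resort guard against numerically singular kernels.
solve_herm <- function(K, B) {
  jitter <- 0
  base <- mean(Re(diag(K)))
  for (attempt in 0:6) {
    res <- tryCatch(solve(K, B), error = function(e) NULL)
    if (!is.null(res)) return(res)
    jitter <- if (jitter == 0) 1e-12 * base else jitter * 100
    diag(K) <- diag(K) + jitter
  }
  stop("singular kernel in M-FOCUSS solve")
}

Matrix_conj_crossprod <- function(Phi, Y) Conj(t(Phi)) %*% (Y + 0i)

frob <- function(x) sqrt(sum(Mod(x)^2))

new_spectral_frame <- function(X, Y, dict, iterations, converged,
                               objective = NULL) {
  S <- Mod(X)^2
  structure(list(X = X, S = S, row_norm = sqrt(rowSums(S)),
                 residual = frob(Y - Re(dict$Phi %*% X)),
                 iterations = iterations, converged = converged,
                 objective = objective, M = dict$M, N = dict$N,
                 H = ncol(X)),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf(
    "<spectral_frame> N=%d grid x H=%d channels; %d active rows; %s in %d it.\n",
    x$N, x$H, sum(x$row_norm > 0), if (x$converged) "converged" else "NOT converged",
    x$iterations))
  invisible(x)
}

#' Power spectrum of a spectral frame
#'
#' Elementwise squared modulus of the sparse coefficient matrix:
#' `S[i, h] = |X[i, h]|^2`.
#'
#' @param frame a `spectral_frame` (or a complex matrix `X`).
#' @return nonnegative N x H matrix.
#' @export
power_spectrum <- function(frame) {
  X <- if (inherits(frame, "spectral_frame")) frame$X else frame
  Mod(X)^2
}

#' Fold a grid bin onto the sub-Nyquist half of the grid
#'
#' Real-valued measurements place conjugate-mirror energy at bin `N - n`;
#' folding maps both members of a pair to `min(n, N - n)` so supports can be
#' compared on the physical (0..N/2) half of the grid.
#'
#' @param bin 0-based bin index (vectorized).
#' @param N grid size.
#' @return folded 0-based bin index.
#' @export
fold_bin <- function(bin, N) pmin(bin %% N, (N - bin) %% N)

#' Active support of a spectral frame, folded to the sub-Nyquist grid
#'
#' @param frame a `spectral_frame`.
#' @param rel_thresh rows with norm below this fraction of the maximum are
#'   ignored.
#' @return sorted 0-based folded bin indices.
#' @export
support_bins <- function(frame, rel_thresh = 1e-3) {
  rn <- frame$row_norm
  idx <- which(rn > rel_thresh * max(rn)) - 1L
  sort(unique(fold_bin(idx, frame$N)))
}
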