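# Motion reference extraction: PCA of the three acceleration channels via
# standardization -> correlation matrix -> cyclic Jacobi eigensolver -> first
# principal-component scores.

#' Standardize channels to zero mean, unit variance
#'
#' @param channels k x M numeric matrix, one channel per row.
#' @return matrix of the same shape; each row has mean 0 and sample
#'   variance 1.
#' @export
standardize <- function(channels) {
  channels <- as.matrix(channels)
  v <- apply(channels, 1L, var)
  if (any(v <= 0 | !is.finite(v))) {
    stop(structure(class = c("ppghr_degenerate_channel", "error", "condition"),
                   list(message = paste0("zero-variance channel(s): ",
                                         paste(which(v <= 0), collapse = ", ")),
                        call = sys.call(-1))))
  }
  sweep(sweep(channels, 1L, rowMeans(channels)), 1L, sqrt(v), "/")
}

#' Correlation coefficient matrix of standardized channels
#'
#' @param channels k x M standardized matrix (see [standardize()]).
#' @return k x k symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(channels) {
  channels <- as.matrix(channels)
  m <- ncol(channels)
  s <- tcrossprod(channels) / (m - 1)
  # enforce exact symmetry and unit diagonal against rounding
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Eigen-decomposition of a symmetric matrix by cyclic Jacobi rotations
#'
#' Performs cyclic sweeps of Givens rotations until every off-diagonal entry
#' is below `tol` (1e-12), then sorts eigenpairs by descending eigenvalue.
#'
#' @param S symmetric numeric matrix.
#' @param tol off-diagonal convergence threshold.
#' @param max_sweeps sweep limit.
#' @return list with `values` (descending) and `vectors` (columns,
#'   orthonormal).
#' @export
jacobi_eig <- function(S, tol = 1e-12, max_sweeps = 100L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n) stop("matrix must be square")
  if (max(abs(S - t(S))) > 1e-9) stop("matrix is not symmetric")
  A <- (S + t(S)) / 2
  V <- diag(n)
  scale0 <- max(abs(A), 1)
  for (sweep in seq_len(max_sweeps)) {
    off <- max(abs(A[upper.tri(A)]))
    if (off < tol * scale0) break
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        if (abs(A[p, q]) < tol * scale0) next
        theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
        t_ <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
        if (theta == 0) t_ <- 1
        c_ <- 1 / sqrt(t_^2 + 1)
        s_ <- t_ * c_
        G <- diag(n); G[p, p] <- c_; G[q, q] <- c_
        G[p, q] <- s_; G[q, p] <- -s_
        A <- crossprod(G, A %*% G)
        A[p, q] <- 0; A[q, p] <- 0
        V <- V %*% G
      }
    }
  }
  vals <- diag(A)
  ord <- order(vals, decreasing = TRUE)
  list(values = vals[ord], vectors = V[, ord, drop = FALSE])
}

#' First principal-component motion reference
#'
#' Standardizes the three acceleration channels of one analysis window,
#' eigen-decomposes their correlation matrix with [jacobi_eig()], and projects
#' onto the leading eigenvector to obtain the reference motion-artifact
#' series. The reference is re-standardized to unit variance and
#' sign-normalized so that its correlation with the first acceleration
#' channel is non-negative.
#'
#' @param accel_window 3 x M numeric matrix.
#' @return list of class `pca_reference`: `scores` (length-M reference),
#'   `eigenvalues` (3, descending), `eigenvectors` (3 x 3, orthonormal
#'   columns), `explained_ratio` (leading eigenvalue / 3), `degenerate`
#'   (TRUE when a zero reference was substituted).
#' @export
first_pc_reference <- function(accel_window) {
  accel_window <- as.matrix(accel_window)
  stopifnot(nrow(accel_window) == 3L)
  m <- ncol(accel_window)
  std <- tryCatch(standardize(accel_window),
                  ppghr_degenerate_channel = function(e) NULL)
  if (is.null(std)) {
    warning("degenerate acceleration window (zero variance); ",
            "substituting a zero motion reference")
    return(structure(list(scores = numeric(m),
                          eigenvalues = c(NA_real_, NA_real_, NA_real_),
                          eigenvectors = diag(3),
                          explained_ratio = NA_real_,
                          degenerate = TRUE),
                     class = "pca_reference"))
  }
  eg <- jacobi_eig(correlation_matrix(std))
  scores <- drop(crossprod(eg$vectors[, 1L], std))
  # sign convention: non-negative correlation with the first accel channel
  if (sum(scores * std[1L, ]) < 0) scores <- -scores
  v <- var(scores)
  if (v > 0) scores <- scores / sqrt(v)
  structure(list(scores = scores,
                 eigenvalues = eg$values,
                 eigenvectors = eg$vectors,
                 explained_ratio = eg$values[1L] / 3,
                 degenerate = FALSE),
            class = "pca_reference")
}
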