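test_that("standardization centers and scales each channel", {
  ch <- rbind(c(1, 2, 3), c(10, 20, 60), c(-4, 0, 4))
  z <- standardize(ch)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, var) - 1)), 1e-10)
  # idempotence
  expect_lt(max(abs(standardize(z) - z)), 1e-12)
  # constant channel is flagged as degenerate
  expect_error(standardize(rbind(c(5, 5, 5), c(1, 2, 3), c(0, 1, 0))),
               class = "ppghr_degenerate_channel")
})

test_that("correlation matrix has the exact structure on constructed channels", {
  x <- with_seed(2, rnorm(1e4))
  same <- standardize(rbind(x, x, rnorm(1e4)))
  r <- correlation_matrix(same)
  expect_equal(r[1, 2], 1)
  opp <- standardize(rbind(x, -x, rnorm(1e4)))
  expect_equal(correlation_matrix(opp)[1, 2], -1)
  # independent noise channels: off-diagonals near zero (Monte Carlo)
  ind <- standardize(matrix(with_seed(3, rnorm(3e4)), 3))
  ri <- correlation_matrix(ind)
  expect_lt(max(abs(ri[upper.tri(ri)])), 0.05)
  expect_equal(diag(ri), rep(1, 3))
  expect_true(all(abs(ri) <= 1 + 1e-12))
})

test_that("Jacobi eigensolver matches closed forms and a dense reference", {
  e1 <- jacobi_eig(diag(c(1, 2, 3)))
  expect_equal(e1$values, c(3, 2, 1))
  e2 <- jacobi_eig(matrix(c(2, 1, 1, 2), 2))
  expect_equal(e2$values, c(3, 1))
  expect_error(jacobi_eig(matrix(c(1, 2, 0, 1), 2)), "not symmetric")

  for (seed in 1:5) {
    A <- with_seed(seed, {m <- matrix(rnorm(9), 3); (m + t(m)) / 2})
    ours <- jacobi_eig(A)
    ref <- eigen(A, symmetric = TRUE)
    expect_equal(ours$values, ref$values, tolerance = 1e-8)
    # eigenvector check up to sign: residual of the eigen equation
    for (j in 1:3) {
      expect_lt(max(abs(A %*% ours$vectors[, j] -
                          ours$values[j] * ours$vectors[, j])), 1e-8)
    }
    # orthonormality
    expect_lt(max(abs(crossprod(ours$vectors) - diag(3))), 1e-8)
  }
})

test_that("first principal component recovers a shared latent motion", {
  m <- 500
  s <- with_seed(4, sin(2 * pi * 1.9 * (1:m) / 25 + 0.3))
  noise <- with_seed(5, matrix(rnorm(3 * m, sd = 0.02), 3))
  accel <- outer(c(1, 0.9, 0.8), s) + noise
  ref <- first_pc_reference(accel)
  expect_gte(abs(cor(ref$scores, s)), 0.99)
  expect_gte(ref$explained_ratio, 0.95)
  # trace conservation
  expect_lt(abs(sum(ref$eigenvalues) - 3), 1e-6)
  # sign convention: non-negative correlation with the first channel
  expect_gte(cor(ref$scores, accel[1, ]), 0)
  # unit variance for the LMS stage
  expect_equal(var(ref$scores), 1, tolerance = 1e-10)
})

test_that("identical channels give eigenvalues (3, 0, 0) and a proportional reference", {
  x <- with_seed(6, rnorm(300))
  ref <- first_pc_reference(rbind(x, x, x))
  expect_equal(ref$eigenvalues, c(3, 0, 0), tolerance = 1e-8)
  expect_gte(abs(cor(ref$scores, x)), 1 - 1e-10)
})

test_that("all-degenerate windows fall back to a zero reference with a warning", {
  expect_warning(ref <- first_pc_reference(matrix(0, 3, 100)), "zero motion")
  expect_true(ref$degenerate)
  expect_equal(ref$scores, numeric(100))
})

test_that("explained ratio is invariant to rotations of the accelerometer axes", {
  m <- 400
  # near-rank-1 motion: correlation-based PCA is rotation invariant only in
  # the strong-common-signal regime, so keep the noise small
  base <- with_seed(7, {
    s <- sin(2 * pi * 2.2 * (1:m) / 25)
    outer(c(1, 0.7, 0.4), s) + matrix(rnorm(3 * m, sd = 1e-4), 3)
  })
  q <- with_seed(8, qr.Q(qr(matrix(rnorm(9), 3))))
  r1 <- first_pc_reference(base)
  r2 <- first_pc_reference(q %*% base)
  expect_equal(r1$explained_ratio, r2$explained_ratio, tolerance = 1e-6)
})
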