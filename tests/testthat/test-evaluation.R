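test_that("average absolute error and percentage match hand arithmetic", {
  expect_equal(aae(c(101, 103), c(100, 100)), 2)
  expect_equal(aae(c(90, 120), c(90, 120)), 0)
  expect_equal(aae(90, 100), 10)
  expect_error(aae(1:3, 1:2), "length")

  expect_equal(aaep(110, 100), 10)
  expect_equal(aaep(c(95, 180), c(95, 180)), 0)
  expect_equal(aaep(c(99, 101), c(100, 100)), 1)
  expect_error(aaep(c(100), c(0)), "strictly positive")
})

test_that("Bland-Altman uses sample sd and 1.96 limits", {
  ba <- bland_altman(c(101, 99), c(100, 100))   # d = (1, -1)
  expect_equal(ba$u, 0)
  expect_equal(ba$sigma, sqrt(2), tolerance = 1e-10)
  expect_equal(ba$loa, c(-1.96 * sqrt(2), 1.96 * sqrt(2)), tolerance = 1e-10)

  ba2 <- bland_altman(c(103, 105, 108), c(100, 102, 105))  # constant d = 3
  expect_equal(ba2$u, 3); expect_equal(ba2$sigma, 0)
  expect_equal(ba2$loa, c(3, 3))

  x <- c(88, 92, 130)
  ba3 <- bland_altman(x, x)
  expect_equal(unlist(ba3), c(u = 0, sigma = 0, loa1 = 0, loa2 = 0),
               ignore_attr = TRUE)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Pearson correlation behaves as the affine-invariant agreement measure", {
  x <- c(80, 95, 120, 150, 160)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(-x + 7, x), -1)
  expect_equal(pearson(0.994 * x + 0.957, x), 1, tolerance = 1e-12)
  expect_error(pearson(rep(100, 5), x), "constant")
})

test_that("metric invariants hold on random traces", {
  with_seed(51, {
    truth <- runif(40, 70, 170)
    est <- truth + rnorm(40, sd = 3)
  })
  # translation detection
  expect_equal(aae(truth + 2.5, truth), 2.5)
  # Bland-Altman mean consistency
  ba <- bland_altman(est, truth)
  expect_equal(ba$u, mean(est) - mean(truth), tolerance = 1e-12)
  # AAEP sandwich
  a <- aae(est, truth)
  p <- aaep(est, truth)
  expect_lte(p, a / min(truth) * 100 + 1e-12)
  expect_gte(p, a / max(truth) * 100 - 1e-12)
})

test_that("cross-validation scores separable data perfectly and chance data near 50%", {
  with_seed(52, {
    feats <- rbind(data.frame(C = runif(60, 0.8, 1), S = runif(60, 0, 0.05)),
                   data.frame(C = runif(60, 0, 0.3), S = runif(60, 0.5, 1)))
    labels <- rep(c(1L, 0L), each = 60)
  })
  expect_equal(as.numeric(cross_validate(feats, labels, k = 10, seed = 3)),
               100)
  shuffled <- with_seed(53, sample(labels))
  acc <- as.numeric(cross_validate(feats, shuffled, k = 10, seed = 3))
  expect_gte(acc, 40); expect_lte(acc, 60)
  expect_error(cross_validate(feats, labels, k = 1), "at least 2")
  expect_error(cross_validate(feats[1:12, ], rep(c(0L, 1L), 6), k = 10),
               "fewer than k")
})

test_that("evaluation reports bundle and serialize the metrics", {
  with_seed(54, {
    truth <- runif(30, 80, 160)
    est <- truth + rnorm(30, sd = 2)
  })
  rep_ <- evaluate_trace(est, truth, cv_accuracy = 93.5)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$aae, aae(est, truth))
  expect_equal(rep_$n_windows, 30)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_report(rep_, tmp)
  txt <- readLines(tmp)
  expect_true(any(grepl("^aae_bpm:", txt)))
  expect_true(any(grepl("^cv_accuracy_percent:", txt)))

  pdir <- withr::local_tempdir()
  files <- plot_agreement(est, truth, pdir)
  expect_true(all(file.exists(file.path(pdir, c("bland_altman.pdf",
                                                "scatter.pdf")))))
})
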