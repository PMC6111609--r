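make_series <- function(scores, hop_s = 0.01) {
  structure(list(scores = scores, labels = NULL, class_ids = 0:(ncol(scores) - 1L),
                 hop_s = hop_s), class = "score_series")
}

test_that("frame counting picks the majority call class, silence excluded", {
  expect_identical(count_classify(c(1L, 1L, 2L, 0L, 0L)), 1L)
  expect_identical(count_classify(c(1L, 2L)), 1L)   # lowest-index tie rule
  expect_identical(count_classify(c(0L, 3L, 3L, 2L)), 3L)
  expect_error(count_classify(c(0L, 0L, 0L)), class = "callscore_unclassifiable")
  expect_error(count_classify(integer(0)), class = "callscore_invalid_input")

  # short-call failure mode: misclassified noise frames outnumber the
  # genuine short-call frames, so counting returns the wrong class
  fig4 <- c(rep(0L, 150), rep(1L, 30), rep(2L, 10))
  expect_identical(count_classify(fig4), 1L)  # true class of the fixture is 2
})

test_that("the whole-series ESD obeys its Fourier identities", {
  expect_true(all(score_series_esd(numeric(64)) == 0))

  const <- score_series_esd(rep(0.5, 256))
  expect_equal(const[1], (0.5 * 256)^2)
  expect_true(all(const[-1] < 1e-18))

  s <- sin(2 * pi * 8 * (0:255) / 256)
  esd <- score_series_esd(s)
  expect_identical(which.max(esd), 9L)  # bin 8 (zero-based)
  nfft <- attr(esd, "nfft")
  two_sided <- esd[1] + esd[nfft / 2 + 1] + 2 * sum(esd[2:(nfft / 2)])
  expect_equal(two_sided, nfft * sum(s^2), tolerance = 1e-9)

  expect_error(score_series_esd(1), class = "callscore_too_short")
})

test_that("linear filterbank uses the 0..Nyquist linear grid with a floor", {
  cfg <- lfcc_config()
  centers <- linear_filter_centers(0.01, cfg)
  expect_equal(centers, seq(0, 50, length.out = 22)[2:21], tolerance = 1e-9)
  expect_equal(max(centers), 50 * 20 / 21)

  zero <- linear_filterbank_log_energies(score_series_esd(numeric(128)), 0.01, cfg)
  expect_true(all(zero == log(cfg$log_floor)))

  # energy concentrated inside filter 5's support maximizes filter 5
  esd <- structure(numeric(129), nfft = 256L)
  bin_freqs <- (0:128) * 100 / 256
  esd[which.min(abs(bin_freqs - centers[5]))] <- 1
  fbe <- linear_filterbank_log_energies(esd, 0.01, cfg)
  expect_identical(which.max(fbe), 5L)
})

test_that("LFCC vectors have one 13-block per call class in class order", {
  set.seed(71)
  scores <- matrix(runif(200 * 5), 200, 5)
  scores <- scores / rowSums(scores)
  series <- make_series(scores)
  v <- lfcc(series)
  expect_length(v, 52)   # 13 x 4, silence column excluded
  expect_identical(v, lfcc(series))
  expect_true(all(is.finite(v)))
  expect_identical(names(v)[1:13], paste0("c1_", 1:13))
  expect_identical(names(v)[40:52], paste0("c4_", 1:13))

  # permuting the class columns permutes the 13-blocks correspondingly
  m <- scores[, 2:5]
  perm <- c(3, 1, 4, 2)
  v1 <- lfcc(m, hop_s = 0.01)
  v2 <- lfcc(m[, perm], hop_s = 0.01)
  for (j in seq_along(perm)) {
    expect_equal(unname(v2[(j - 1) * 13 + 1:13]),
                 unname(v1[(perm[j] - 1) * 13 + 1:13]))
  }
})

test_that("truncated-cepstrum reconstruction error shrinks with more terms", {
  set.seed(81)
  ref <- rnorm(20)
  full <- reconstruct_filterbank(ref, 20)
  expect_lt(full$rmse, 1e-9)
  expect_equal(full$reconstruction, ref, tolerance = 1e-9)

  const <- reconstruct_filterbank(rep(2.5, 20), 1)
  expect_lt(const$rmse, 1e-9)   # all energy in c0

  rmse <- vapply(1:20, function(n) reconstruct_filterbank(ref, n)$rmse, numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
  expect_error(reconstruct_filterbank(ref, 0), class = "callscore_invalid_input")
  expect_error(reconstruct_filterbank(ref, 21), class = "callscore_invalid_input")
})

test_that("raising the log floor never widens the filterbank dynamic range", {
  set.seed(91)
  for (i in 1:10) {
    s <- runif(100) * rbinom(100, 1, 0.7)
    lo <- linear_filterbank_log_energies(score_series_esd(s), 0.01,
                                         lfcc_config(log_floor = 1e-12))
    hi <- linear_filterbank_log_energies(score_series_esd(s), 0.01,
                                         lfcc_config(log_floor = 1e-6))
    expect_lte(diff(range(hi)), diff(range(lo)) + 1e-12)
  }
})

test_that("LFCC CSV export keeps names and one row per recording", {
  set.seed(73)
  scores <- matrix(runif(64 * 3), 64, 3)
  v1 <- lfcc(scores, hop_s = 0.01)
  v2 <- lfcc(scores[, c(2, 3, 1)], hop_s = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lfcc_csv(list(v1, v2), path, recording_ids = c("a", "b"))
  back <- read.csv(path, check.names = FALSE)
  expect_identical(dim(back), c(2L, 40L))
  expect_identical(names(back)[2], "c1_1")
  expect_equal(as.numeric(back[1, -1]), unname(v1), tolerance = 1e-12)
})

test_that("second-stage classification recovers recording labels", {
  set.seed(95)
  # separable LFCC clusters: one tight blob per class
  centers <- matrix(rnorm(3 * 52, sd = 3), 3, 52)
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rnorm(10 * 52, sd = 0.1), 10, 52) +
      matrix(centers[i, ], 10, 52, byrow = TRUE)
  }))
  y <- rep(1:3, each = 10)
  model <- fit_classifier(x, y, classifier_spec("MinDis"))
  expect_identical(score_classify(x, model), as.integer(y))
  expect_identical(score_classify(x[5, ], model), 1L)
})
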