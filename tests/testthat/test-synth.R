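test_that("generation is deterministic and respects the configured class mix", {
  cfg <- tiny_config(12, seed = 3)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(lapply(d1, `[[`, "samples"), lapply(d2, `[[`, "samples"))
  expect_identical(lapply(d1, `[[`, "rois"), lapply(d2, `[[`, "rois"))

  # heavy-imbalance mix at the full dataset size: counts within 3 sd
  cfg868 <- tiny_config(868, seed = 11, duration = 0.3)
  labels <- vapply(generate_dataset(cfg868), `[[`, integer(1), "class_label")
  p <- cfg868$class_proportions
  counts <- tabulate(labels, nbins = 4)
  expect_true(all(abs(counts - 868 * p) <= 3 * sqrt(868 * p * (1 - p))))
})

test_that("class proportions converge with n (chi-square not rejected)", {
  # A single fixed-seed chi-square rejects spuriously ~1% of the time by
  # construction; three independent replicates are combined with Fisher's
  # method so the invariant is tested at the intended alpha = 0.01 level.
  ps <- vapply(21:23, function(s) {
    cfg <- tiny_config(5000, seed = s, duration = 0.3)
    labels <- vapply(generate_dataset(cfg), `[[`, integer(1), "class_label")
    stats::chisq.test(tabulate(labels, nbins = 4),
                      p = cfg$class_proportions)$p.value
  }, numeric(1))
  combined <- stats::pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                            lower.tail = FALSE)
  expect_gt(combined, 0.01)
})

test_that("disabling noise leaves the signal outside ROIs exactly zero", {
  cfg <- tiny_config(6, seed = 5, snr = Inf)
  for (rec in generate_dataset(cfg)) {
    fs <- rec$sample_rate
    outside <- rep(TRUE, length(rec$samples))
    for (r in rec$rois) {
      outside[(floor(r[1] * fs) + 1):min(length(outside), ceiling(r[2] * fs))] <- FALSE
    }
    expect_true(all(rec$samples[outside] == 0))
  }
})

test_that("measure_snr matches the closed form and the configured level", {
  fs <- 1000
  x <- c(rep(0.5, 100), rep(sqrt(0.025), 100))
  rec <- audio_recording(x, fs, class_label = 1L, rois = list(c(0, 0.1)))
  expect_equal(measure_snr(rec), 10 * log10(0.25 / 0.025), tolerance = 1e-9)

  silent_out <- audio_recording(c(rep(0.5, 100), rep(0, 100)), fs,
                                class_label = 1L, rois = list(c(0, 0.1)))
  expect_identical(measure_snr(silent_out), Inf)

  all_roi <- audio_recording(rep(0.5, 100), fs, class_label = 1L,
                             rois = list(c(0, 0.1)))
  expect_error(measure_snr(all_roi), class = "callscore_undefined_snr")
  no_roi <- audio_recording(rep(0.5, 100), fs, class_label = 1L)
  expect_error(measure_snr(no_roi), class = "callscore_undefined_snr")

  # Monte-Carlo: a dataset generated at 10 dB measures 10 +/- 1 dB
  ds <- generate_dataset(tiny_config(100, seed = 9, duration = 1))
  measured <- vapply(ds, measure_snr, numeric(1))
  expect_lt(abs(mean(measured) - 10), 1)
})

test_that("frame labelling follows the 50 percent ROI-overlap rule", {
  fs <- 8000
  cfg <- mfcc_config()
  rec <- audio_recording(numeric(3 * fs), fs, class_label = 2L,
                         rois = list(c(0.5, 1.5)))
  labels <- label_frames(rec, cfg)

  # brute-force overlap per frame
  win_s <- floor(cfg$window_ms * fs / 1000) / fs
  hop_s <- floor(cfg$hop_ms * fs / 1000) / fs
  expected <- vapply(seq_along(labels), function(i) {
    a <- (i - 1) * hop_s; b <- a + win_s
    ov <- max(0, min(b, 1.5) - max(a, 0.5))
    if (ov >= 0.5 * win_s) 2L else 0L
  }, integer(1))
  expect_identical(labels, expected)
  expect_gt(sum(labels == 2L), 0)

  # a frame fully inside the ROI carries the class, 40% overlap does not
  inside <- which(vapply(seq_along(labels), function(i) {
    a <- (i - 1) * hop_s; (a >= 0.5) && (a + win_s <= 1.5)
  }, logical(1)))
  expect_true(all(labels[inside] == 2L))
  rec40 <- audio_recording(numeric(fs), fs, class_label = 1L,
                           rois = list(c(0, 0.4 * win_s)))
  expect_identical(label_frames(rec40, cfg)[1], 0L)
})

test_that("generated recordings satisfy the container invariants", {
  for (seed in c(2, 17, 33)) {
    cfg <- tiny_config(8, seed = seed, duration = stats::runif(1, 0.4, 0.8))
    for (rec in generate_dataset(cfg)) {
      dur <- length(rec$samples) / rec$sample_rate
      expect_true(all(abs(rec$samples) <= 1))
      starts <- vapply(rec$rois, `[`, numeric(1), 1)
      ends <- vapply(rec$rois, `[`, numeric(1), 2)
      expect_true(all(starts >= 0 & ends <= dur + 1e-9 & starts < ends))
      if (length(starts) > 1) {
        expect_true(all(starts[-1] >= ends[-length(ends)] - 1e-12))
      }
      expect_true(rec$class_label %in% 1:4)
    }
  }
})

test_that("degenerate configurations and containers are rejected", {
  expect_error(synth_config(0), class = "callscore_invalid_config")
  expect_error(synth_config(5, class_proportions = c(0.5, 0.4)),
               class = "callscore_invalid_config")
  expect_error(tiny_config(5, duration = 0.01),
               class = "callscore_invalid_config")
  expect_error(audio_recording(numeric(0), 8000),
               class = "callscore_invalid_recording")
  expect_error(
    audio_recording(numeric(100), 100, class_label = 1L,
                    rois = list(c(0, 0.5), c(0.3, 0.8))),
    class = "callscore_invalid_recording")
})

test_that("WAV, ROI and manifest round trips preserve the dataset", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(tiny_config(4, seed = 13))

  write_wav(ds[[1]], file.path(dir, "a.wav"), format = "float32")
  back <- read_wav(file.path(dir, "a.wav"))
  expect_equal(back$sample_rate, ds[[1]]$sample_rate)
  expect_equal(back$samples, ds[[1]]$samples, tolerance = 1e-7)

  write_wav(ds[[1]], file.path(dir, "b.wav"), format = "pcm16")
  back16 <- read_wav(file.path(dir, "b.wav"))
  expect_lt(max(abs(back16$samples - ds[[1]]$samples)), 1 / 32767)

  write_dataset(ds, file.path(dir, "set"))
  rt <- read_dataset(file.path(dir, "set"))
  expect_length(rt, 4)
  expect_identical(vapply(rt, `[[`, integer(1), "class_label"),
                   vapply(ds, `[[`, integer(1), "class_label"))
  expect_equal(rt[[2]]$rois, ds[[2]]$rois, tolerance = 1e-9)
  expect_lt(max(abs(rt[[3]]$samples - ds[[3]]$samples)), 1 / 32767)
})
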