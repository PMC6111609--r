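# Small, fast generator configurations used across the tests: modest sample
# rates and short recordings, carriers inside the 300-3700 Hz analysis band.

tiny_templates <- function(background_calls2 = 0L) {
  list(
    call_template(600, 40, 120, calls_per_recording = 2),
    call_template(1000, 90, 60, calls_per_recording = 2,
                  background_calls = background_calls2),
    call_template(1400, 12, 100, calls_per_recording = 2),
    call_template(1800, 120, 80, calls_per_recording = 1)
  )
}

tiny_config <- function(n, seed = 1L, duration = 0.5, fs = 8000, snr = 10,
                        props = c(0.43, 0.07, 0.48, 0.02), ...) {
  synth_config(n, class_proportions = props,
               class_templates = tiny_templates(...),
               recording_duration_s = duration, noise_snr_db = snr,
               sample_rate = fs, seed = seed)
}

# Widely separated, long, loud calls: every stage should classify this
# perfectly.
separable_config <- function(n = 28L, seed = 1L) {
  synth_config(n, class_proportions = rep(0.25, 4),
               class_templates = list(
                 call_template(500, 30, 300, calls_per_recording = 2),
                 call_template(1200, 70, 300, calls_per_recording = 2),
                 call_template(2000, 15, 300, calls_per_recording = 2),
                 call_template(3000, 110, 300, calls_per_recording = 2)),
               recording_duration_s = 1.5, noise_snr_db = 30,
               sample_rate = 8000, seed = seed)
}

# Gaussian blob features for classifier-contract tests.
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, y = rep(seq_len(nrow(centers)) - 1L, each = n_per))
}
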