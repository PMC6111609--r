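#' Audio recording container
#'
#' Bundles a mono waveform with its sample rate, class label, and
#' region-of-interest (ROI) annotations.  ROIs are half-open `[start_s,
#' end_s)` intervals marking where the labelled call is actually present;
#' everything outside them is silence or background noise.
#'
#' @param samples Numeric waveform with values in \[-1, 1\].
#' @param sample_rate Sample rate in Hz.
#' @param class_label Integer class in `1..C`, or `NA` if unknown.
#' @param rois List of length-2 numeric vectors `c(start_s, end_s)`.
#' @param id Optional recording identifier.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate, class_label = NA_integer_,
                            rois = list(), id = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop_callscore("recording must contain at least one sample", "callscore_invalid_recording")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop_callscore("sample_rate must be positive", "callscore_invalid_recording")
  }
  if (any(abs(samples) > 1 + 1e-9)) {
    stop_callscore("waveform values must lie in [-1, 1]", "callscore_invalid_recording")
  }
  duration <- length(samples) / sample_rate
  if (length(rois) > 0L) {
    m <- do.call(rbind, lapply(rois, as.numeric))
    if (ncol(m) != 2L || any(m[, 1] >= m[, 2])) {
      stop_callscore("ROIs must be (start_s, end_s) with start < end", "callscore_invalid_recording")
    }
    if (any(m[, 1] < 0) || any(m[, 2] > duration + 1e-9)) {
      stop_callscore("ROIs must lie within [0, duration)", "callscore_invalid_recording")
    }
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2] - 1e-12)) {
      stop_callscore("ROIs must be pairwise non-overlapping", "callscore_invalid_recording")
    }
    rois <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 class_label = as.integer(class_label), rois = rois, id = id),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.3f s @ %d Hz, class %s, %d ROI(s)\n",
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate),
              ifelse(is.na(x$class_label), "?", x$class_label), length(x$rois)))
  invisible(x)
}

#' Spectro-temporal call template
#'
#' Describes how calls of one class are rendered: an amplitude-modulated
#' sinusoidal pulse train at a class-specific carrier frequency.
#'
#' @param carrier_hz Carrier frequency in Hz.
#' @param pulse_rate_hz Amplitude-modulation (pulse) rate in Hz.
#' @param call_ms Call duration in milliseconds.
#' @param calls_per_recording Number of calls rendered per recording.
#' @param amp_range Per-call peak amplitude range (uniform draw).
#' @param background_calls Number of faint, *unannotated* calls of the
#'   dataset's background class mixed into the soundscape of this class's
#'   recordings (distant-chorus interference; see Details).
#' @param background_amp_range Amplitude range of those background calls.
#'
#' @details Background calls emulate distant conspecific choruses recorded
#'   behind the focal animal: they belong acoustically to another class but
#'   are not annotated as ROIs, so under frame counting they inflate the
#'   wrong class's frame count.  For very short focal calls this reproduces
#'   the characteristic failure of frame counting on minority classes.
#' @return An object of class `call_template`.
#' @export
call_template <- function(carrier_hz, pulse_rate_hz, call_ms,
                          calls_per_recording = 1L, amp_range = c(0.3, 1),
                          background_calls = 0L,
                          background_amp_range = c(0.15, 0.35)) {
  stopifnot(carrier_hz > 0, pulse_rate_hz > 0, call_ms > 0,
            calls_per_recording >= 1, length(amp_range) == 2L,
            amp_range[1] > 0, amp_range[2] <= 1, amp_range[1] <= amp_range[2])
  structure(list(carrier_hz = carrier_hz, pulse_rate_hz = pulse_rate_hz,
                 call_ms = call_ms,
                 calls_per_recording = as.integer(calls_per_recording),
                 amp_range = amp_range,
                 background_calls = as.integer(background_calls),
                 background_amp_range = background_amp_range),
            class = "call_template")
}

#' Default four-class anuran-like call templates
#'
#' Loosely modelled on the vocal repertoire of the natterjack toad
#' (*Epidalea calamita*) and the common midwife toad (*Alytes
#' obstetricans*): a long pulsed mating call, a very short release call, a
#' short repeated whistle, and a high-pitched distress call.  The release
#' call (class 2) is kept under 300 ms and its recordings carry faint
#' background mating-call interference, so that noise frames mistaken for
#' class 1 can outnumber genuine class-2 frames.
#'
#' @return A list of four [call_template()] objects.
#' @export
default_call_templates <- function() {
  list(
    call_template(1400, 40, 800, calls_per_recording = 2),
    call_template(1800, 90, 250, calls_per_recording = 3,
                  background_calls = 2),
    call_template(1100, 12, 350, calls_per_recording = 4),
    call_template(2600, 120, 500, calls_per_recording = 1)
  )
}

#' Synthetic dataset configuration
#'
#' @param n_recordings Number of recordings to generate.
#' @param class_proportions Probability vector over the C call classes;
#'   defaults to the heavy imbalance typical of field-recorded anuran
#'   datasets (43/7/48/2 percent).
#' @param class_templates List of C [call_template()] objects.
#' @param recording_duration_s Recording duration in seconds.
#' @param noise_snr_db Target in-ROI to out-of-ROI power ratio in dB;
#'   `Inf` disables noise.
#' @param sample_rate Sample rate in Hz.
#' @param pink_noise If `TRUE`, use 1/f (pink) rather than white Gaussian
#'   background noise.
#' @param background_class Class whose calls are used as unannotated
#'   background interference (see [call_template()]).
#' @param seed Master seed; per-recording streams are derived from it by
#'   counter splitting, so each recording's waveform is independent of
#'   generation order.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_recordings,
                         class_proportions = c(0.43, 0.07, 0.48, 0.02),
                         class_templates = default_call_templates(),
                         recording_duration_s = 5,
                         noise_snr_db = 10,
                         sample_rate = 44100,
                         pink_noise = FALSE,
                         background_class = 1L,
                         seed = 1L) {
  if (length(class_proportions) < 1L || n_recordings < 1L) {
    stop_callscore("need at least one class and one recording", "callscore_invalid_config")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop_callscore("class_proportions must be nonnegative and sum to 1", "callscore_invalid_config")
  }
  if (length(class_templates) != length(class_proportions)) {
    stop_callscore("one template per class required", "callscore_invalid_config")
  }
  if (recording_duration_s <= 0 || sample_rate <= 0) {
    stop_callscore("durations and rates must be positive", "callscore_invalid_config")
  }
  for (tpl in class_templates) {
    if (tpl$call_ms / 1000 > recording_duration_s) {
      stop_callscore("call duration exceeds recording duration", "callscore_invalid_config")
    }
  }
  structure(list(n_recordings = as.integer(n_recordings),
                 class_proportions = class_proportions,
                 class_templates = class_templates,
                 recording_duration_s = recording_duration_s,
                 noise_snr_db = noise_snr_db,
                 sample_rate = sample_rate,
                 pink_noise = isTRUE(pink_noise),
                 background_class = as.integer(background_class),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Render one amplitude-modulated sinusoidal pulse of `n` samples.
render_pulse <- function(n, fs, carrier_hz, pulse_rate_hz, amp, phase) {
  t <- (seq_len(n) - 1L) / fs
  env <- 0.5 * (1 - cos(2 * pi * pulse_rate_hz * t))
  ramp_n <- min(n %/% 2L, max(1L, floor(0.005 * fs)))
  taper <- rep(1, n)
  r <- seq_len(ramp_n)
  taper[r] <- 0.5 * (1 - cos(pi * (r - 1L) / ramp_n))
  taper[n + 1L - r] <- taper[r]
  amp * env * taper * sin(2 * pi * carrier_hz * t + phase)
}

# Place m non-overlapping intervals of length len_s inside [0, dur_s) by
# stick-breaking over the free time (deterministic given the RNG stream).
place_calls <- function(m, len_s, dur_s) {
  free <- dur_s - m * len_s
  if (free < 0) stop_callscore("calls do not fit in the recording", "callscore_invalid_config")
  gaps <- runif(m + 1L)
  gaps <- gaps / sum(gaps) * free
  starts <- cumsum(gaps[seq_len(m)]) + (seq_len(m) - 1L) * len_s
  starts
}

pink_noise_samples <- function(n, sd) {
  # Spectral synthesis: white spectrum shaped by 1/sqrt(f), unit-variance
  # normalized, then scaled.
  nfft <- next_pow2(n)
  half <- nfft %/% 2L
  mag <- c(0, 1 / sqrt(seq_len(half)))
  phase <- runif(half + 1L, 0, 2 * pi)
  spec <- mag * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:half])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x <- x / stats::sd(x)
  x * sd
}

#' Generate a labelled synthetic call dataset
#'
#' Draws class labels from the configured proportions, renders each
#' recording's calls as amplitude-modulated pulse trains on the class
#' carrier, annotates the call intervals as ROIs, and adds background noise
#' at the configured SNR.  Identical configurations (including seed) give
#' bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list of [audio_recording()] objects.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_recordings
  C <- length(config$class_proportions)
  labels <- with_local_seed(config$seed,
    sample.int(C, n, replace = TRUE, prob = config$class_proportions))
  lapply(seq_len(n), function(i) {
    with_local_seed(derive_seed(config$seed, i),
                    render_recording(labels[i], config, id = sprintf("rec%04d", i)))
  })
}

render_recording <- function(class_label, config, id = NULL) {
  fs <- config$sample_rate
  dur <- config$recording_duration_s
  n <- round(dur * fs)
  tpl <- config$class_templates[[class_label]]
  len_s <- tpl$call_ms / 1000
  len_n <- round(len_s * fs)
  signal <- numeric(n)
  starts <- place_calls(tpl$calls_per_recording, len_s, dur)
  rois <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    amp <- runif(1, tpl$amp_range[1], tpl$amp_range[2])
    i0 <- floor(starts[j] * fs) + 1L
    i1 <- min(n, i0 + len_n - 1L)
    signal[i0:i1] <- signal[i0:i1] +
      render_pulse(i1 - i0 + 1L, fs, tpl$carrier_hz, tpl$pulse_rate_hz,
                   amp, runif(1, 0, 2 * pi))
    rois[[j]] <- c((i0 - 1L) / fs, i1 / fs)
  }
  in_roi <- logical(n)
  for (r in rois) in_roi[(floor(r[1] * fs) + 1L):min(n, ceiling(r[2] * fs))] <- TRUE
  p_roi <- mean(signal[in_roi]^2)
  # Unannotated background interference from another class's repertoire.
  if (tpl$background_calls > 0L) {
    btpl <- config$class_templates[[config$background_class]]
    blen_n <- round(btpl$call_ms / 1000 * fs)
    for (j in seq_len(tpl$background_calls)) {
      for (try in seq_len(50L)) {
        s0 <- sample.int(n - blen_n + 1L, 1L)
        span <- c((s0 - 1L) / fs, (s0 + blen_n - 1L) / fs)
        clear <- all(vapply(rois, function(r) {
          span[2] <= r[1] || span[1] >= r[2]
        }, logical(1)))
        if (clear) {
          amp <- runif(1, tpl$background_amp_range[1], tpl$background_amp_range[2])
          idx <- s0:(s0 + blen_n - 1L)
          signal[idx] <- signal[idx] +
            render_pulse(blen_n, fs, btpl$carrier_hz, btpl$pulse_rate_hz,
                         amp, runif(1, 0, 2 * pi))
          break
        }
      }
    }
  }
  snr <- config$noise_snr_db
  if (is.finite(snr)) {
    # sd chosen so the expected measured in-ROI/out-of-ROI power ratio
    # (signal + noise over noise) hits the target.
    noise_var <- p_roi / (10^(snr / 10) - 1)
    noise <- if (config$pink_noise) {
      pink_noise_samples(n, sqrt(noise_var))
    } else {
      rnorm(n, 0, sqrt(noise_var))
    }
    x <- signal + noise
  } else {
    x <- signal
  }
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * (0.99 / peak)
  audio_recording(x, fs, class_label = class_label, rois = rois, id = id)
}

#' Measure the in-ROI to out-of-ROI power ratio
#'
#' @param recording An [audio_recording()] with at least one ROI sample and
#'   at least one non-ROI sample.
#' @return SNR in dB: `10 * log10(mean in-ROI power / mean out-of-ROI
#'   power)`.  `Inf` if the out-of-ROI region is exactly silent.
#' @export
measure_snr <- function(recording) {
  stopifnot(inherits(recording, "audio_recording"))
  n <- length(recording$samples)
  fs <- recording$sample_rate
  in_roi <- logical(n)
  for (r in recording$rois) {
    in_roi[(floor(r[1] * fs) + 1L):min(n, ceiling(r[2] * fs))] <- TRUE
  }
  if (!any(in_roi) || all(in_roi)) {
    stop_callscore("SNR undefined: recording must have both ROI and non-ROI samples",
                   "callscore_undefined_snr")
  }
  p_in <- mean(recording$samples[in_roi]^2)
  p_out <- mean(recording$samples[!in_roi]^2)
  if (p_out == 0) return(Inf)
  10 * log10(p_in / p_out)
}

#' Project ROI annotations onto a frame grid
#'
#' Mechanizes expert frame labelling: a frame is given the recording's
#' class label iff at least half of its span overlaps an ROI; otherwise it
#' is labelled 0 (silence/noise).
#'
#' @param recording An [audio_recording()].
#' @param config An [mfcc_config()] (only `window_ms` and `hop_ms` are used).
#' @return Integer vector of per-frame labels in `0..C`, one per frame of
#'   [frame_signal()]'s grid.
#' @export
label_frames <- function(recording, config = mfcc_config()) {
  fs <- recording$sample_rate
  win <- floor(config$window_ms * fs / 1000)
  hop <- floor(config$hop_ms * fs / 1000)
  n <- length(recording$samples)
  if (n < win) stop_callscore("recording shorter than one frame", "callscore_too_short")
  n_frames <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop / fs
  win_s <- win / fs
  labels <- integer(n_frames)
  if (length(recording$rois) == 0L || is.na(recording$class_label)) return(labels)
  for (i in seq_len(n_frames)) {
    a <- starts[i]; b <- a + win_s
    ov <- 0
    for (r in recording$rois) ov <- ov + max(0, min(b, r[2]) - max(a, r[1]))
    if (ov >= 0.5 * win_s) labels[i] <- recording$class_label
  }
  labels
}
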