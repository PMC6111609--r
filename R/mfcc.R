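#' MFCC extraction configuration (HTK dialect)
#'
#' Defaults follow the HTK conventions for vocal sound: 0.97 pre-emphasis,
#' 25 ms Hamming windows with a 10 ms hop, a 20-filter triangular mel
#' filterbank between 300 and 3700 Hz, an orthonormal DCT-II keeping
#' coefficients c1..c13 (c0 dropped), and a sine lifter with L = 22.
#'
#' @param preemphasis_alpha Pre-emphasis constant in \[0, 1).
#' @param window_ms Analysis window length (ms).
#' @param hop_ms Hop size (ms); must not exceed `window_ms`.
#' @param window_function Only `"hamming"` is supported.
#' @param n_filters Number of triangular mel filters.
#' @param band_low_hz,band_high_hz Filterbank band edges (Hz).
#' @param n_ceps_full Number of DCT coefficients computed.
#' @param n_ceps_kept Number of cepstral coefficients kept (D).
#' @param lifter_L Sine-lifter constant; `0` disables liftering.
#' @param log_floor Filterbank energies below this are clamped before the
#'   log, keeping features finite on silent frames.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(preemphasis_alpha = 0.97, window_ms = 25, hop_ms = 10,
                        window_function = "hamming", n_filters = 20L,
                        band_low_hz = 300, band_high_hz = 3700,
                        n_ceps_full = 20L, n_ceps_kept = 13L, lifter_L = 22L,
                        log_floor = 1e-12) {
  if (preemphasis_alpha < 0 || preemphasis_alpha >= 1) {
    stop_callscore("preemphasis_alpha must be in [0, 1)", "callscore_invalid_config")
  }
  if (hop_ms <= 0 || hop_ms > window_ms) {
    stop_callscore("need 0 < hop_ms <= window_ms", "callscore_invalid_config")
  }
  if (band_low_hz >= band_high_hz) {
    stop_callscore("band_low_hz must be below band_high_hz", "callscore_invalid_config")
  }
  if (n_ceps_kept < 1 || n_ceps_kept > n_ceps_full || n_ceps_full > n_filters) {
    stop_callscore("need 0 < D <= n_ceps_full <= n_filters", "callscore_invalid_config")
  }
  if (n_ceps_kept >= n_filters) {
    stop_callscore("D must be below n_filters (c0 is dropped)", "callscore_invalid_config")
  }
  if (!identical(tolower(window_function), "hamming")) {
    stop_callscore("only the Hamming window is supported", "callscore_invalid_config")
  }
  structure(list(preemphasis_alpha = preemphasis_alpha, window_ms = window_ms,
                 hop_ms = hop_ms, window_function = "hamming",
                 n_filters = as.integer(n_filters), band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz,
                 n_ceps_full = as.integer(n_ceps_full),
                 n_ceps_kept = as.integer(n_ceps_kept),
                 lifter_L = as.integer(lifter_L), log_floor = log_floor),
            class = "mfcc_config")
}

#' First-order pre-emphasis filter
#'
#' `y[n] = x[n] - alpha * x[n-1]`, with the HTK first-sample convention
#' `y[1] = (1 - alpha) * x[1]`.
#'
#' @param signal Numeric waveform.
#' @param alpha Pre-emphasis constant.
#' @return Filtered waveform of the same length.
#' @export
preemphasize <- function(signal, alpha = 0.97) {
  if (length(signal) == 0L) {
    stop_callscore("empty signal", "callscore_invalid_signal")
  }
  c(signal[1L] * (1 - alpha),
    if (length(signal) > 1L) signal[-1L] - alpha * signal[-length(signal)])
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Split a signal into Hamming-windowed frames
#'
#' Frames of `floor(window_ms * fs / 1000)` samples advanced by
#' `floor(hop_ms * fs / 1000)` samples; trailing samples that do not fill a
#' whole window are dropped.
#'
#' @param signal Numeric waveform.
#' @param sample_rate Sample rate in Hz.
#' @param config An [mfcc_config()].
#' @return A `win x n_frames` matrix of windowed frames, with attributes
#'   `frame_times_s` (frame start times) and `hop_s`.
#' @export
frame_signal <- function(signal, sample_rate, config = mfcc_config()) {
  win <- floor(config$window_ms * sample_rate / 1000)
  hop <- floor(config$hop_ms * sample_rate / 1000)
  n <- length(signal)
  if (n < win) stop_callscore("signal shorter than one window", "callscore_too_short")
  n_frames <- (n - win) %/% hop + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(signal[idx], nrow = win) * hamming_window(win)
  attr(frames, "frame_times_s") <- (seq_len(n_frames) - 1L) * hop / sample_rate
  attr(frames, "hop_s") <- hop / sample_rate
  frames
}

#' Energy spectral density of a frame
#'
#' Squared-magnitude one-sided discrete Fourier spectrum, with FFT length
#' the next power of two at or above the frame length (zero-padded).
#'
#' @param frame Numeric vector (a windowed frame).
#' @return Nonnegative vector of length `nfft/2 + 1`, with attribute `nfft`.
#' @export
energy_spectral_density <- function(frame) {
  if (length(frame) == 0L) stop_callscore("empty frame", "callscore_invalid_signal")
  r <- esd_one_sided(frame)
  structure(r$esd, nfft = r$nfft)
}

#' Mel scale conversions
#'
#' `hz_to_mel(f) = 2595 * log10(1 + f / 700)` and its inverse.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in mel.
#' @return Numeric vector.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Mel filterbank weight matrix for a given nfft and sample rate.
mel_filterbank <- function(sample_rate, nfft, config) {
  if (config$band_high_hz > sample_rate / 2) {
    stop_callscore("filterbank band exceeds the Nyquist frequency", "callscore_invalid_config")
  }
  edges <- mel_to_hz(seq(hz_to_mel(config$band_low_hz),
                         hz_to_mel(config$band_high_hz),
                         length.out = config$n_filters + 2L))
  bin_freqs <- (0:(nfft %/% 2L)) * sample_rate / nfft
  triangular_filterbank(edges, bin_freqs)
}

#' Mel filterbank center frequencies
#'
#' @param config An [mfcc_config()].
#' @return The `n_filters` center frequencies in Hz.
#' @export
mel_filter_centers <- function(config = mfcc_config()) {
  edges <- mel_to_hz(seq(hz_to_mel(config$band_low_hz),
                         hz_to_mel(config$band_high_hz),
                         length.out = config$n_filters + 2L))
  edges[2:(config$n_filters + 1L)]
}

#' Log mel filterbank energies of one ESD
#'
#' @param esd Output of [energy_spectral_density()] (the `nfft` attribute
#'   is required unless `nfft` is given).
#' @param sample_rate Sample rate in Hz.
#' @param config An [mfcc_config()].
#' @param nfft FFT length used to compute `esd`.
#' @return Natural-log filterbank energies (length `n_filters`), floored at
#'   `log(config$log_floor)`.
#' @export
mel_filterbank_log_energies <- function(esd, sample_rate, config = mfcc_config(),
                                        nfft = attr(esd, "nfft")) {
  fb <- mel_filterbank(sample_rate, nfft, config)
  log(pmax(as.numeric(fb %*% as.numeric(esd)), config$log_floor))
}

# Sine lifter gains for coefficients c1..cD.
lifter_gains <- function(D, L) {
  if (L <= 0) return(rep(1, D))
  1 + (L / 2) * sin(pi * seq_len(D) / L)
}

#' Cepstrum of a log filterbank energy vector
#'
#' Orthonormal DCT-II of the log energies; coefficients `c1..cD` are kept
#' (`c0`, the overall level, is dropped) and liftered by
#' `c'_n = (1 + (L/2) sin(pi n / L)) c_n`.
#'
#' @param log_energies Numeric vector of length `config$n_filters`.
#' @param config An [mfcc_config()].
#' @return Numeric vector of length `config$n_ceps_kept`.
#' @export
cepstrum <- function(log_energies, config = mfcc_config()) {
  if (any(!is.finite(log_energies))) {
    stop_callscore("log energies must be finite", "callscore_invalid_signal")
  }
  co <- dct2(log_energies)[seq_len(config$n_ceps_full)]
  kept <- co[1L + seq_len(config$n_ceps_kept)]  # skip c0
  kept * lifter_gains(config$n_ceps_kept, config$lifter_L)
}

#' Extract the MFCC feature matrix of a recording
#'
#' Composition of pre-emphasis, Hamming framing, energy spectral density,
#' log mel filterbank, DCT-II and sine liftering.
#'
#' @param recording An [audio_recording()], or a numeric waveform (then
#'   `sample_rate` must be given).
#' @param config An [mfcc_config()].
#' @param sample_rate Sample rate in Hz for bare waveforms.
#' @return An object of class `frame_features`: a list with `values`
#'   (`n_frames x D` matrix), `frame_times_s`, `hop_s`, and `config`.
#' @export
extract_mfcc <- function(recording, config = mfcc_config(), sample_rate = NULL) {
  if (inherits(recording, "audio_recording")) {
    signal <- recording$samples
    sample_rate <- recording$sample_rate
  } else {
    signal <- as.numeric(recording)
    if (is.null(sample_rate)) stop("sample_rate required for a bare waveform")
  }
  pre <- preemphasize(signal, config$preemphasis_alpha)
  frames <- frame_signal(pre, sample_rate, config)
  win <- nrow(frames)
  nfft <- next_pow2(win)
  padded <- rbind(frames, matrix(0, nfft - win, ncol(frames)))
  spec <- stats::mvfft(padded)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  esd <- Re(spec)^2 + Im(spec)^2
  fb <- mel_filterbank(sample_rate, nfft, config)
  log_e <- log(pmax(fb %*% esd, config$log_floor))
  dct_rows <- dct_matrix(config$n_filters)[1L + seq_len(config$n_ceps_kept), , drop = FALSE]
  ceps <- t(dct_rows %*% log_e) *
    rep(lifter_gains(config$n_ceps_kept, config$lifter_L),
        each = ncol(log_e))
  colnames(ceps) <- paste0("c", seq_len(config$n_ceps_kept))
  structure(list(values = ceps,
                 frame_times_s = attr(frames, "frame_times_s"),
                 hop_s = attr(frames, "hop_s"),
                 config = config),
            class = "frame_features")
}

#' @export
print.frame_features <- function(x, ...) {
  cat(sprintf("<frame_features> %d frames x %d coefficients (hop %.3f s)\n",
              nrow(x$values), ncol(x$values), x$hop_s))
  invisible(x)
}

#' Write frame features as CSV
#'
#' Columnar table with header `t_s,c1..cD`.
#'
#' @param features A `frame_features` object from [extract_mfcc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(t_s = features$frame_times_s, features$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
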