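#' LFCC configuration for score-series features
#'
#' Cepstral representation of a classifier's per-class score series: the
#' whole series (no windowing) is Fourier-transformed, passed through a
#' 20-filter triangular bank on a *linear* frequency grid from 0 Hz to the
#' series Nyquist, logged, and decorrelated with an orthonormal DCT-II of
#' which coefficients c1..c13 are kept.  Unlike sound MFCCs there is no
#' pre-emphasis, no band filtering, no mel scaling and no liftering: score
#' series are not sounds.
#'
#' @param n_filters Number of triangular filters.
#' @param n_ceps_full Number of DCT coefficients computed.
#' @param n_ceps_kept Number of cepstral coefficients kept per class (D).
#' @param log_floor Filter energies below this are clamped before the log,
#'   so all-zero score series yield finite features instead of minus
#'   infinity.
#' @return An object of class `lfcc_config`.
#' @export
lfcc_config <- function(n_filters = 20L, n_ceps_full = 20L, n_ceps_kept = 13L,
                        log_floor = 1e-12) {
  if (n_ceps_kept < 1 || n_ceps_kept > n_ceps_full || n_ceps_full > n_filters) {
    stop_callscore("need 0 < D <= n_ceps_full <= n_filters", "callscore_invalid_config")
  }
  if (n_ceps_kept >= n_filters) {
    stop_callscore("D must be below n_filters (c0 is dropped)", "callscore_invalid_config")
  }
  structure(list(n_filters = as.integer(n_filters),
                 n_ceps_full = as.integer(n_ceps_full),
                 n_ceps_kept = as.integer(n_ceps_kept),
                 log_floor = log_floor),
            class = "lfcc_config")
}

#' Label a recording by counting frame labels
#'
#' The baseline recording-level rule: the class (silence excluded) with the
#' most frames wins; ties go to the lowest class index.  A recording whose
#' frames are all silence/noise is unclassifiable and raises a
#' `callscore_unclassifiable` condition.
#'
#' @param series A [classify_frames()] result, or an integer vector of
#'   frame labels in `0..C`.
#' @return Integer class label in `1..C`.
#' @export
count_classify <- function(series) {
  labels <- if (inherits(series, "score_series")) series$labels else as.integer(series)
  if (length(labels) < 1L) stop_callscore("empty series", "callscore_invalid_input")
  counts <- tabulate(labels[labels > 0L])
  if (length(counts) == 0L || all(counts == 0L)) {
    stop_callscore("all frames are silence/noise: recording unclassifiable",
                   "callscore_unclassifiable")
  }
  which.max(counts)
}

#' Energy spectral density of one class's score series
#'
#' The series is taken as a whole (no windowing) and zero-padded to the
#' next power of two.
#'
#' @param series Numeric vector of per-frame scores for one class
#'   (length >= 2).
#' @return Nonnegative vector of length `nfft/2 + 1` with attribute `nfft`.
#' @export
score_series_esd <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L) {
    stop_callscore("score series must have at least two frames", "callscore_too_short")
  }
  r <- esd_one_sided(series)
  structure(r$esd, nfft = r$nfft)
}

#' Linear filterbank center frequencies
#'
#' Edges equally spaced from 0 Hz to the score-series Nyquist frequency
#' `1 / (2 * hop_s)`; centers are `m * nyquist / (n_filters + 1)` for
#' `m = 1..n_filters`.
#'
#' @param hop_s Frame hop in seconds.
#' @param config An [lfcc_config()].
#' @return Numeric vector of center frequencies in Hz.
#' @export
linear_filter_centers <- function(hop_s, config = lfcc_config()) {
  nyquist <- 1 / (2 * hop_s)
  seq(0, nyquist, length.out = config$n_filters + 2L)[2:(config$n_filters + 1L)]
}

#' Log linear filterbank energies of a score-series ESD
#'
#' @param esd Output of [score_series_esd()] (attribute `nfft` required
#'   unless given).
#' @param hop_s Frame hop in seconds (sets the series Nyquist).
#' @param config An [lfcc_config()].
#' @param nfft FFT length used for `esd`.
#' @return Natural-log filter energies (length `n_filters`), floored at
#'   `log(config$log_floor)`.
#' @export
linear_filterbank_log_energies <- function(esd, hop_s, config = lfcc_config(),
                                           nfft = attr(esd, "nfft")) {
  fs <- 1 / hop_s
  edges <- seq(0, fs / 2, length.out = config$n_filters + 2L)
  bin_freqs <- (0:(nfft %/% 2L)) * fs / nfft
  fb <- triangular_filterbank(edges, bin_freqs)
  log(pmax(as.numeric(fb %*% as.numeric(esd)), config$log_floor))
}

#' LFCC feature vector of a score series
#'
#' For each of the C call classes (the silence/noise column is excluded:
#' its scores are redundant given the others), the class's score series is
#' transformed to D cepstral coefficients and the per-class blocks are
#' concatenated in class order, giving a `D x C`-long recording-level
#' feature vector.
#'
#' @param series A [classify_frames()] result, or a plain numeric matrix of
#'   scores (then `hop_s` is required and *all* columns are treated as call
#'   classes).
#' @param config An [lfcc_config()].
#' @param hop_s Frame hop in seconds for plain matrices.
#' @return Numeric vector of length `D * C`, named `c<class>_<k>`.
#' @export
lfcc <- function(series, config = lfcc_config(), hop_s = NULL) {
  if (inherits(series, "score_series")) {
    keep <- series$class_ids != 0L
    scores <- series$scores[, keep, drop = FALSE]
    class_ids <- series$class_ids[keep]
    hop_s <- series$hop_s
  } else {
    scores <- as.matrix(series)
    class_ids <- seq_len(ncol(scores))
    if (is.null(hop_s)) stop("hop_s required for a plain score matrix")
  }
  if (ncol(scores) < 1L) {
    stop_callscore("at least one call-class score column required", "callscore_invalid_input")
  }
  D <- config$n_ceps_kept
  dct_rows <- dct_matrix(config$n_filters)[1L + seq_len(D), , drop = FALSE]
  out <- numeric(0)
  for (j in seq_len(ncol(scores))) {
    esd <- score_series_esd(scores[, j])
    fb <- linear_filterbank_log_energies(esd, hop_s, config)
    out <- c(out, as.numeric(dct_rows %*% fb))
  }
  names(out) <- as.vector(outer(seq_len(D), class_ids,
                                function(k, cl) paste0("c", cl, "_", k)))
  out
}

#' Reconstruct a filterbank spectrum from truncated cepstra
#'
#' Measures how well the first `n` of the 20 cepstral coefficients
#' represent a log filterbank energy vector: coefficients beyond `n`
#' (counting c0 as the first) are zeroed and the inverse DCT is compared
#' with the reference.
#'
#' @param reference Numeric log filterbank energy vector.
#' @param n Number of leading cepstral coefficients kept (1..length).
#' @return A list with `reconstruction` and `rmse`.
#' @export
reconstruct_filterbank <- function(reference, n) {
  m <- length(reference)
  if (n < 1 || n > m) {
    stop_callscore("n must be between 1 and the filterbank size", "callscore_invalid_input")
  }
  co <- dct2(reference)
  co[seq_len(m) > n] <- 0
  rec <- idct2(co)
  list(reconstruction = rec, rmse = sqrt(mean((rec - reference)^2)))
}

#' Write LFCC feature vectors as CSV
#'
#' One row per recording with header `recording_id,c<class>_<k>`.
#'
#' @param features A single [lfcc()] vector or a list of them.
#' @param path Output CSV path.
#' @param recording_ids Optional ids (default: sequence).
#' @return `path`, invisibly.
#' @export
write_lfcc_csv <- function(features, path, recording_ids = NULL) {
  if (!is.list(features)) features <- list(features)
  if (is.null(recording_ids)) recording_ids <- seq_along(features)
  m <- do.call(rbind, features)
  df <- data.frame(recording_id = recording_ids, m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classify a recording from its LFCC feature vector
#'
#' Second-stage classification: applies any trained classifier family to
#' the `D x C` score-series features.
#'
#' @param features Numeric LFCC vector (or matrix, one row per recording),
#'   already normalized with the second-stage normalizer.
#' @param model A [fit_classifier()] result trained on LFCC features.
#' @return Integer class label(s) in `1..C`.
#' @export
score_classify <- function(features, model) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  sc <- predict_scores(model, x)
  as.integer(model$levels[max.col(sc, ties.method = "first")])
}
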