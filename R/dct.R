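#' Orthonormal DCT-II matrix
#'
#' Returns the `n` x `n` orthonormal type-II discrete cosine transform
#' matrix `T`, such that `T %*% x` gives the DCT coefficients `c0..c(n-1)`
#' of `x` and `t(T) %*% c` inverts it exactly.
#'
#' @param n Transform length (positive integer).
#' @return An `n` x `n` numeric matrix.
#' @export
dct_matrix <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  k <- 0:(n - 1L)
  m <- outer(k, k, function(k, j) cos(pi * (j + 0.5) * k / n))
  m <- m * sqrt(2 / n)
  m[1L, ] <- m[1L, ] / sqrt(2)
  m
}

# Forward orthonormal DCT-II of a vector.
dct2 <- function(x) as.numeric(dct_matrix(length(x)) %*% x)

# Inverse of the orthonormal DCT-II.
idct2 <- function(c) as.numeric(crossprod(dct_matrix(length(c)), c))

# One-sided energy spectral density of a real vector, zero-padded to the
# next power of two >= length(x).  Returns squared FFT magnitudes for bins
# 0..nfft/2 (length nfft/2 + 1).
esd_one_sided <- function(x, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- next_pow2(n)
  stopifnot(nfft >= n)
  padded <- c(x, numeric(nfft - n))
  spec <- fft(padded)[seq_len(nfft %/% 2L + 1L)]
  list(esd = Re(spec)^2 + Im(spec)^2, nfft = nfft)
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

# Triangular filterbank weight matrix.  `edges` is a vector of n_filters + 2
# increasing frequencies (Hz); `bin_freqs` the frequencies of the spectrum
# bins.  Row i holds filter i's weights: a triangle rising from edges[i]
# to a peak of 1 at edges[i + 1] and falling to edges[i + 2].
triangular_filterbank <- function(edges, bin_freqs) {
  n_filters <- length(edges) - 2L
  w <- matrix(0, n_filters, length(bin_freqs))
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- bin_freqs > lo & bin_freqs <= ce
    down <- bin_freqs > ce & bin_freqs < hi
    w[i, up] <- (bin_freqs[up] - lo) / (ce - lo)
    w[i, down] <- (hi - bin_freqs[down]) / (hi - ce)
  }
  w
}
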