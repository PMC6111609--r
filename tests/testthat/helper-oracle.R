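# Independent brute-force oracles, written straight from the definitions.
# They deliberately share no code with the package implementation.

# HTK-dialect MFCC chain with explicit loops.
oracle_mfcc <- function(signal, fs, alpha = 0.97, window_ms = 25, hop_ms = 10,
                        n_filters = 20, lo = 300, hi = 3700, D = 13, L = 22,
                        floor_ = 1e-12) {
  n <- length(signal)
  y <- numeric(n)
  y[1] <- (1 - alpha) * signal[1]
  if (n > 1) for (i in 2:n) y[i] <- signal[i] - alpha * signal[i - 1]
  win <- floor(window_ms * fs / 1000)
  hop <- floor(hop_ms * fs / 1000)
  nf <- floor((n - win) / hop) + 1
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  nfft <- 2^ceiling(log2(win))
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(mel(lo) + (0:(n_filters + 1)) * (mel(hi) - mel(lo)) / (n_filters + 1))
  freqs <- (0:(nfft / 2)) * fs / nfft
  out <- matrix(0, nf, D)
  for (fr in seq_len(nf)) {
    seg <- y[((fr - 1) * hop + 1):((fr - 1) * hop + win)] * ham
    sp <- fft(c(seg, rep(0, nfft - win)))
    esd <- Mod(sp[1:(nfft / 2 + 1)])^2
    lfbe <- numeric(n_filters)
    for (m in seq_len(n_filters)) {
      w <- numeric(length(freqs))
      for (b in seq_along(freqs)) {
        f <- freqs[b]
        if (f > pts[m] && f <= pts[m + 1]) {
          w[b] <- (f - pts[m]) / (pts[m + 1] - pts[m])
        } else if (f > pts[m + 1] && f < pts[m + 2]) {
          w[b] <- (pts[m + 2] - f) / (pts[m + 2] - pts[m + 1])
        }
      }
      lfbe[m] <- log(max(sum(w * esd), floor_))
    }
    for (k in seq_len(D)) {
      ck <- sqrt(2 / n_filters) *
        sum(lfbe * cos(pi * k * ((1:n_filters) - 0.5) / n_filters))
      out[fr, k] <- (1 + (L / 2) * sin(pi * k / L)) * ck
    }
  }
  out
}

# Per-definition metric computation: explicit one-vs-rest 2x2 collapse and
# the triple-sum multiclass correlation.
oracle_global_metrics <- function(cm) {
  cm <- as.matrix(cm)
  C <- nrow(cm); m <- sum(cm)
  sns <- spc <- prc <- npv <- f1 <- gm <- bm <- mk <- numeric(C)
  for (i in seq_len(C)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- m - tp - fn - fp
    sns[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spc[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prc[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    npv[i] <- if (tn + fn > 0) tn / (tn + fn) else 0
    f1[i] <- if (!is.na(sns[i]) && prc[i] + sns[i] > 0) {
      2 * prc[i] * sns[i] / (prc[i] + sns[i])
    } else 0
    gm[i] <- sqrt(sns[i] * spc[i])
    bm[i] <- sns[i] + spc[i] - 1
    mk[i] <- prc[i] + npv[i] - 1
  }
  num <- 0
  for (k in seq_len(C)) for (l in seq_len(C)) for (q in seq_len(C)) {
    num <- num + cm[k, k] * cm[l, q] - cm[k, l] * cm[q, k]
  }
  d1 <- 0; d2 <- 0
  for (k in seq_len(C)) {
    d1 <- d1 + sum(cm[k, ]) * sum(cm[-k, ])
    d2 <- d2 + sum(cm[, k]) * sum(cm[, -k])
  }
  mcc <- if (d1 > 0 && d2 > 0) num / (sqrt(d1) * sqrt(d2)) else 0
  c(SNS = mean(sns, na.rm = TRUE), SPC = mean(spc, na.rm = TRUE),
    PRC = mean(prc, na.rm = TRUE), NPV = mean(npv, na.rm = TRUE),
    ACC = sum(diag(cm)) / m, F1 = mean(f1, na.rm = TRUE),
    GM = mean(gm, na.rm = TRUE), MCCn = (mcc + 1) / 2,
    BMn = (mean(bm, na.rm = TRUE) + 1) / 2,
    MKn = (mean(mk, na.rm = TRUE) + 1) / 2)
}

# Exhaustive nearest-centroid search.
oracle_min_distance <- function(x, centroids) {
  apply(x, 1L, function(row) {
    d <- apply(centroids, 1L, function(ce) sqrt(sum((row - ce)^2)))
    which.min(d)
  })
}
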