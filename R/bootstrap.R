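# Fast metric vector from paired labels via a tabulated confusion matrix.
metrics_from_pairs <- function(pair_idx, C, n) {
  counts <- matrix(tabulate(pair_idx, nbins = C * C), C, C)
  global_metrics(as_confusion_matrix(counts))
}

#' Bootstrap confidence intervals for the metric vector
#'
#' Resamples the recordings (not the frames) of a fixed prediction set with
#' replacement, recomputes the ten global metrics per resample, and reports
#' empirical percentile confidence intervals.
#'
#' @param truth,predicted Integer vectors of per-recording true and
#'   predicted labels in `1..C`.
#' @param C Number of classes.
#' @param n_resamples Number of bootstrap resamples (Nb).
#' @param conf_level Confidence level gamma; interval endpoints are the
#'   `(1 - gamma)/2` and `1 - (1 - gamma)/2` percentiles.
#' @param seed Seed controlling the resampling.
#' @return An object of class `bootstrap_result`: list with
#'   `metric_samples` (`Nb x 10`), `observed`, `mean`, `ci_low`, `ci_high`,
#'   `n_resamples`, `conf_level`, `seed`.
#' @export
bootstrap_metrics <- function(truth, predicted, C = max(truth, predicted),
                              n_resamples = 10000L, conf_level = 0.95,
                              seed = 1L) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  S <- length(truth)
  if (S < 2L || length(predicted) != S) {
    stop_callscore("need >= 2 paired predictions", "callscore_invalid_input")
  }
  pair_idx <- truth + C * (predicted - 1L)
  samples <- with_local_seed(seed, {
    t(vapply(seq_len(n_resamples), function(b) {
      metrics_from_pairs(pair_idx[sample.int(S, S, replace = TRUE)], C, S)
    }, numeric(10L)))
  })
  colnames(samples) <- metric_names()
  alpha <- (1 - conf_level) / 2
  structure(list(metric_samples = samples,
                 observed = metrics_from_pairs(pair_idx, C, S),
                 mean = colMeans(samples),
                 ci_low = apply(samples, 2L, quantile, probs = alpha, names = FALSE),
                 ci_high = apply(samples, 2L, quantile, probs = 1 - alpha, names = FALSE),
                 n_resamples = as.integer(n_resamples),
                 conf_level = conf_level, seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> Nb = %d, conf = %.2f\n",
              x$n_resamples, x$conf_level))
  print(round(data.frame(observed = x$observed, mean = x$mean,
                         ci_low = x$ci_low, ci_high = x$ci_high), 4))
  invisible(x)
}

#' Paired bootstrap outperformance probability
#'
#' Both methods' predictions over the *same* recordings are resampled with
#' identical resample indices; for each resample the metric-vector
#' difference `delta = mu1 - mu2` is computed, and the outperformance
#' probability `o_k` is the fraction of resamples with `delta_k`
#' strictly positive (ties contribute zero, so a method compared against
#' itself scores 0, not 0.5).
#'
#' @param truth True labels in `1..C`.
#' @param predicted1,predicted2 The two methods' predictions.
#' @param C Number of classes.
#' @param n_resamples Number of bootstrap resamples.
#' @param conf_level Confidence level for the difference intervals.
#' @param seed Resampling seed.
#' @return An object of class `outperformance_result`: list with
#'   `delta_samples` (`Nb x 10`), `delta_mean`, `delta_observed`,
#'   `ci_low`, `ci_high`, `prob_outperform`.
#' @export
outperformance <- function(truth, predicted1, predicted2,
                           C = max(truth, predicted1, predicted2),
                           n_resamples = 10000L, conf_level = 0.95,
                           seed = 1L) {
  truth <- as.integer(truth)
  S <- length(truth)
  if (length(predicted1) != S || length(predicted2) != S) {
    stop_callscore("both methods must cover the same recordings", "callscore_invalid_input")
  }
  idx1 <- truth + C * (as.integer(predicted1) - 1L)
  idx2 <- truth + C * (as.integer(predicted2) - 1L)
  delta <- with_local_seed(seed, {
    t(vapply(seq_len(n_resamples), function(b) {
      r <- sample.int(S, S, replace = TRUE)   # shared: paired design
      metrics_from_pairs(idx1[r], C, S) - metrics_from_pairs(idx2[r], C, S)
    }, numeric(10L)))
  })
  colnames(delta) <- metric_names()
  alpha <- (1 - conf_level) / 2
  structure(list(delta_samples = delta,
                 delta_observed = metrics_from_pairs(idx1, C, S) -
                   metrics_from_pairs(idx2, C, S),
                 delta_mean = colMeans(delta),
                 ci_low = apply(delta, 2L, quantile, probs = alpha, names = FALSE),
                 ci_high = apply(delta, 2L, quantile, probs = 1 - alpha, names = FALSE),
                 prob_outperform = colMeans(delta > 0),
                 n_resamples = as.integer(n_resamples),
                 conf_level = conf_level, seed = as.integer(seed)),
            class = "outperformance_result")
}

#' @export
print.outperformance_result <- function(x, ...) {
  cat(sprintf("<outperformance_result> Nb = %d\n", x$n_resamples))
  print(round(data.frame(delta_mean = x$delta_mean, ci_low = x$ci_low,
                         ci_high = x$ci_high,
                         pr_outperform = x$prob_outperform), 4))
  invisible(x)
}

#' Bootstrap report as a JSON-ready list
#'
#' Per-metric mean, confidence interval, and (when an
#' [outperformance()] result is supplied) outperformance probability, laid
#' out as Mean / Conf. Int. / Pr. Outperf.
#'
#' @param boot A [bootstrap_metrics()] result.
#' @param outperf Optional [outperformance()] result.
#' @return A named list, one entry per metric.
#' @export
bootstrap_report <- function(boot, outperf = NULL) {
  out <- lapply(seq_along(metric_names()), function(k) {
    entry <- list(mean = unname(boot$mean[k]),
                  conf_int = c(unname(boot$ci_low[k]), unname(boot$ci_high[k])))
    if (!is.null(outperf)) {
      entry$pr_outperform <- unname(outperf$prob_outperform[k])
    }
    entry
  })
  names(out) <- metric_names()
  out
}
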