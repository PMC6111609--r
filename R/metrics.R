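#' Multiclass confusion matrix
#'
#' `m[i, j]` counts recordings of true class `i` labelled as class `j`.
#'
#' @param truth,predicted Equal-length integer vectors with values in
#'   `1..C`.
#' @param C Number of classes.
#' @return An object of class `confusion_matrix`: the `C x C` integer count
#'   matrix with attributes `row_totals` (true class sizes), `col_totals`
#'   (predicted class sizes) and `total`.
#' @export
confusion_matrix <- function(truth, predicted, C = max(truth, predicted)) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop_callscore("truth and predicted must have equal length", "callscore_invalid_input")
  }
  if (any(truth < 1L | truth > C) || any(predicted < 1L | predicted > C)) {
    stop_callscore("labels must lie in 1..C", "callscore_invalid_input")
  }
  counts <- matrix(tabulate(truth + C * (predicted - 1L), nbins = C * C), C, C)
  as_confusion_matrix(counts)
}

as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  structure(counts,
            row_totals = rowSums(counts), col_totals = colSums(counts),
            total = sum(counts), class = c("confusion_matrix", "matrix"))
}

#' Per-class (one-vs-rest) classification metrics
#'
#' For each class `i` with `m_i` true members, `e_i` predicted members and
#' the one-vs-rest 2x2 collapse of the confusion matrix:
#' sensitivity `SNS_i = m_ii / m_i`, specificity `SPC_i = TN_i / (m - m_i)`,
#' precision `PRC_i = m_ii / e_i`, negative predictive value
#' `NPV_i = TN_i / (m - e_i)`, `F1_i`, geometric mean
#' `GM_i = sqrt(SNS_i * SPC_i)`, bookmaker informedness
#' `BM_i = SNS_i + SPC_i - 1` and markedness `MK_i = PRC_i + NPV_i - 1`
#' (both unnormalized, in \[-1, 1\]).
#'
#' Degenerate conventions: `SNS_i` is `NA` when `m_i = 0` (the class is
#' then excluded from macro averages); `PRC_i = 0` when `e_i = 0`;
#' `F1_i = 0` when `PRC_i + SNS_i = 0`.
#'
#' @param cm A [confusion_matrix()].
#' @return A data frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  pc <- compute_per_class(unclass(cm))
  data.frame(class = seq_len(length(pc$SNS)), SNS = pc$SNS, SPC = pc$SPC,
             PRC = pc$PRC, NPV = pc$NPV, F1 = pc$F1, GM = pc$GM,
             BM = pc$BM, MK = pc$MK)
}

compute_per_class <- function(counts) {
  C <- nrow(counts)
  m_i <- rowSums(counts); e_i <- colSums(counts); m <- sum(counts)
  tp <- diag(counts)
  # TN_i = m - m_i - e_i + m_ii for the one-vs-rest 2x2 collapse
  tn <- m - m_i - e_i + tp
  sns <- ifelse(m_i > 0, tp / m_i, NA_real_)
  spc <- ifelse(m - m_i > 0, tn / (m - m_i), NA_real_)
  prc <- ifelse(e_i > 0, tp / e_i, 0)
  npv <- ifelse(m - e_i > 0, tn / (m - e_i), 0)
  f1 <- ifelse(!is.na(sns) & (prc + sns) > 0, 2 * prc * sns / (prc + sns), 0)
  list(SNS = sns, SPC = spc, PRC = prc, NPV = npv, F1 = f1,
       GM = sqrt(sns * spc), BM = sns + spc - 1, MK = prc + npv - 1)
}

#' Names of the ten global metrics
#'
#' @return Character vector in canonical order.
#' @export
metric_names <- function() {
  c("SNS", "SPC", "PRC", "NPV", "ACC", "F1", "GM", "MCCn", "BMn", "MKn")
}

# Multiclass Matthews correlation (the R_K statistic): covariance between
# prediction and truth indicator matrices, normalized by their variances.
multiclass_mcc <- function(counts) {
  s <- sum(counts)
  c_tr <- sum(diag(counts))
  t_k <- rowSums(counts)   # true class sizes
  p_k <- colSums(counts)   # predicted class sizes
  num <- c_tr * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Global (macro-averaged) classification metrics
#'
#' Macro means of the per-class metrics (classes with no true members are
#' excluded), accuracy from the diagonal, the multiclass Matthews
#' correlation coefficient, and the \[-1, 1\] metrics (MCC, BM, MK) mapped
#' to \[0, 1\] by `(mu + 1) / 2`.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector of the ten metrics, all in \[0, 1\].
#' @export
global_metrics <- function(cm) {
  counts <- unclass(cm)
  pc <- compute_per_class(counts)
  macro <- function(v) mean(v, na.rm = TRUE)
  acc <- sum(diag(counts)) / sum(counts)
  mcc <- multiclass_mcc(counts)
  c(SNS = macro(pc$SNS), SPC = macro(pc$SPC), PRC = macro(pc$PRC),
    NPV = macro(pc$NPV), ACC = acc, F1 = macro(pc$F1),
    GM = macro(pc$GM), MCCn = (mcc + 1) / 2,
    BMn = (macro(pc$BM) + 1) / 2, MKn = (macro(pc$MK) + 1) / 2)
}

#' Reconstruct integer confusion counts from row percentages
#'
#' Published confusion matrices are often printed as row percentages; given
#' the true class totals this inverts the rounding: counts are
#' `round(percent / 100 * total)` with a largest-remainder correction so
#' every row sums exactly to its class total.
#'
#' @param percent `C x C` matrix of row percentages (each row sums to 100
#'   within 0.1).
#' @param class_totals Integer vector of true class sizes.
#' @return A [confusion_matrix()].
#' @export
reconstruct_counts <- function(percent, class_totals) {
  percent <- as.matrix(percent)
  C <- nrow(percent)
  if (length(class_totals) != C || any(class_totals <= 0)) {
    stop_callscore("one positive total per row required", "callscore_invalid_input")
  }
  if (any(abs(rowSums(percent) - 100) > 0.1)) {
    stop_callscore("each percentage row must sum to 100 (within 0.1)", "callscore_invalid_input")
  }
  counts <- matrix(0L, C, C)
  for (i in seq_len(C)) {
    exact <- percent[i, ] / 100 * class_totals[i]
    base <- round(exact)
    deficit <- class_totals[i] - sum(base)
    if (deficit != 0) {
      # push the deficit onto the cells with the largest rounding remainders
      rem <- exact - base
      ord <- order(if (deficit > 0) -rem else rem)
      base[ord[seq_len(abs(deficit))]] <- base[ord[seq_len(abs(deficit))]] + sign(deficit)
    }
    counts[i, ] <- as.integer(base)
  }
  as_confusion_matrix(counts)
}

#' Print a confusion matrix in row-percentage form
#'
#' @param x A [confusion_matrix()].
#' @param digits Decimal places for the percentages.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  counts <- matrix(as.vector(unclass(x)), nrow(x))
  pct <- sweep(counts, 1L, pmax(rowSums(counts), 1L), `/`) * 100
  cat("<confusion_matrix> row percentages (counts in parentheses)\n")
  print(matrix(sprintf(paste0("%.", digits, "f%% (%d)"), pct, counts),
               nrow(counts), ncol(counts)), quote = FALSE)
  invisible(x)
}
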