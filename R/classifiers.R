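#' Fit a per-feature z-score normalizer
#'
#' Computes the mean and standard deviation of every feature over all
#' training frames.  Standard deviations below `sigma_floor` are floored so
#' that constant features in tiny synthetic sets do not blow up.
#'
#' @param features A numeric matrix (frames x features), a `frame_features`
#'   object, or a list of either (rows are pooled).
#' @param sigma_floor Lower bound on the per-feature standard deviation.
#' @return An object of class `feature_normalizer` with fields `mu`, `sigma`.
#' @export
fit_normalizer <- function(features, sigma_floor = 1e-8) {
  x <- pool_feature_rows(features)
  if (nrow(x) < 2L) {
    stop_callscore("need at least two frames to fit a normalizer", "callscore_invalid_input")
  }
  mu <- colMeans(x)
  sigma <- pmax(apply(x, 2L, stats::sd), sigma_floor)
  structure(list(mu = mu, sigma = sigma), class = "feature_normalizer")
}

pool_feature_rows <- function(features) {
  if (inherits(features, "frame_features")) return(features$values)
  if (is.matrix(features)) return(features)
  if (is.list(features)) {
    return(do.call(rbind, lapply(features, pool_feature_rows)))
  }
  if (is.numeric(features)) return(matrix(features, nrow = 1L))
  stop_callscore("unsupported feature container", "callscore_invalid_input")
}

#' Apply a fitted normalizer
#'
#' `x'_ij = (x_ij - mu_j) / sigma_j`.
#'
#' @param features Matrix or `frame_features` whose columns match the
#'   normalizer's dimension.
#' @param normalizer A [fit_normalizer()] result.
#' @return A numeric matrix of normalized features.
#' @export
apply_normalizer <- function(features, normalizer) {
  x <- pool_feature_rows(features)
  if (ncol(x) != length(normalizer$mu)) {
    stop_callscore("feature dimension does not match the normalizer", "callscore_invalid_input")
  }
  sweep(sweep(x, 2L, normalizer$mu, `-`), 2L, normalizer$sigma, `/`)
}

#' Classifier specification
#'
#' Names one of the eight supported supervised families and its
#' hyperparameters.  Families: `MinDis` (nearest centroid), `MaxLik`
#' (per-class Gaussian mixture, 2 components with full covariance by
#' default), `DecTr` (CART decision tree), `kNN` (k = 1 by default),
#' `LogReg` (multinomial logistic regression), `Neur` (feed-forward net,
#' one 10-neuron hidden layer), `Discr` (linear discriminant), `Bayes`
#' (naive Bayes).
#'
#' @param family One of `"MinDis"`, `"MaxLik"`, `"DecTr"`, `"kNN"`,
#'   `"LogReg"`, `"Neur"`, `"Discr"`, `"Bayes"`.
#' @param ... Family-specific hyperparameters: `k` (kNN), `gmm_components`
#'   (MaxLik), `hidden` and `maxit` (Neur), `maxit` (LogReg).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("MinDis", "MaxLik", "DecTr", "kNN",
                                       "LogReg", "Neur", "Discr", "Bayes"),
                            ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    kNN = list(k = 1L),
    MaxLik = list(gmm_components = 2L),
    Neur = list(hidden = 10L, maxit = 200L),
    LogReg = list(maxit = 200L),
    list())
  for (nm in names(defaults)) if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  structure(list(family = family, params = params), class = "classifier_spec")
}

#' All eight classifier families
#'
#' @return Character vector of the family names accepted by
#'   [classifier_spec()].
#' @export
classifier_families <- function() {
  c("MinDis", "MaxLik", "DecTr", "kNN", "LogReg", "Neur", "Discr", "Bayes")
}

#' Train the nearest-centroid (minimum distance) classifier
#'
#' Stores the per-class mean of the (normalized) features.
#'
#' @param features Numeric matrix of normalized features (rows = frames).
#' @param labels Vector of class labels, one per row.
#' @return An object of class `centroid_model` with a `centroids` matrix
#'   (one row per class, rownames = class levels).
#' @export
min_distance_train <- function(features, labels) {
  x <- pool_feature_rows(features)
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  centroids <- t(vapply(lv, function(l) colMeans(x[labels == l, , drop = FALSE]),
                        numeric(ncol(x))))
  if (any(!is.finite(centroids))) {
    stop_callscore("every class needs at least one training frame", "callscore_missing_class")
  }
  structure(list(centroids = centroids, levels = lv), class = "centroid_model")
}

#' Nearest-centroid prediction
#'
#' Euclidean distance to every class centroid; the label is the centroid
#' with the minimum distance (lowest class index on ties) and the score row
#' is `softmax(-d)`.
#'
#' @param features Numeric matrix (or single vector) of normalized features.
#' @param model A [min_distance_train()] result.
#' @return A list with `labels` (character), `scores` (rows summing to 1)
#'   and `distances`.
#' @export
min_distance_predict <- function(features, model) {
  x <- pool_feature_rows(features)
  ce <- model$centroids
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, computed blockwise.
  d2 <- outer(rowSums(x^2), rep(1, nrow(ce))) - 2 * x %*% t(ce) +
    outer(rep(1, nrow(x)), rowSums(ce^2))
  d <- sqrt(pmax(d2, 0))
  scores <- softmax_rows(-d)
  colnames(scores) <- model$levels
  labels <- model$levels[max.col(-d, ties.method = "first")]
  list(labels = labels, scores = scores, distances = d)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# log multivariate normal density with a regularized covariance.
log_dmvnorm <- function(x, mu, sigma) {
  d <- length(mu)
  sigma <- sigma + diag(1e-8, d)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# Per-class Gaussian mixture likelihood model with graceful fallbacks for
# degenerate training sets (few frames, near-singular covariances).
fit_maxlik <- function(x, y, levels, components) {
  fits <- lapply(levels, function(l) {
    xi <- x[y == l, , drop = FALSE]
    fit <- NULL
    if (nrow(xi) > 2L * ncol(xi)) {
      fit <- tryCatch(
        mclust::densityMclust(xi, G = components, modelNames = "VVV",
                              verbose = FALSE, plot = FALSE),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(fit$loglik) || !is.finite(fit$loglik))) fit <- NULL
    }
    if (is.null(fit)) {
      # single regularized Gaussian fallback
      list(kind = "gauss", mu = colMeans(xi),
           sigma = stats::cov(xi) * (nrow(xi) - 1L) / max(1L, nrow(xi)))
    } else {
      list(kind = "mclust", fit = fit)
    }
  })
  names(fits) <- levels
  fits
}

predict_maxlik_log <- function(fits, x) {
  sapply(fits, function(f) {
    if (f$kind == "mclust") {
      lp <- log(pmax(predict(f$fit, x), 1e-300))
    } else {
      lp <- log_dmvnorm(x, f$mu, f$sigma)
    }
    lp
  })
}

#' Train a frame (or score-series) classifier
#'
#' Dispatches to the family named by the spec.  Features are expected to be
#' already normalized (see [fit_normalizer()]).  The degenerate one-class
#' case yields a constant classifier.
#'
#' @param features Numeric matrix of training rows.
#' @param labels Class labels (coerced to factor; keep level order
#'   meaningful — lowest level wins score ties).
#' @param spec A [classifier_spec()].
#' @param seed Optional seed for stochastic trainers (neural net).
#' @return An object of class `callscore_model`.
#' @export
fit_classifier <- function(features, labels, spec, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- pool_feature_rows(features)
  y <- factor(labels)
  levels <- levels(y)
  if (nrow(x) != length(y)) {
    stop_callscore("one label per feature row required", "callscore_invalid_input")
  }
  if (length(levels) == 1L) {
    return(structure(list(spec = spec, levels = levels, fit = NULL,
                          constant = levels), class = "callscore_model"))
  }
  df <- data.frame(.y = y, x)
  fit <- with_local_seed(seed, switch(spec$family,
    MinDis = min_distance_train(x, y),
    MaxLik = fit_maxlik(x, as.character(y), levels, spec$params$gmm_components),
    DecTr = rpart::rpart(.y ~ ., data = df, method = "class"),
    kNN = list(x = x, y = y, k = as.integer(spec$params$k)),
    LogReg = nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            maxit = spec$params$maxit,
                            MaxNWts = 100000L),
    Neur = nnet::nnet(x, nnet::class.ind(y), size = spec$params$hidden,
                      softmax = TRUE, maxit = spec$params$maxit,
                      trace = FALSE, MaxNWts = 100000L),
    Discr = MASS::lda(x, grouping = y),
    Bayes = e1071::naiveBayes(x, y)
  ))
  structure(list(spec = spec, levels = levels, fit = fit, constant = NULL),
            class = "callscore_model")
}

# kNN vote proportions by chunked exact neighbour search (k = 1 delegates
# to class::knn's C implementation).
predict_knn_scores <- function(fit, x, levels) {
  k <- fit$k
  if (k == 1L) {
    lab <- as.character(class::knn(fit$x, x, fit$y, k = 1L))
    sc <- matrix(0, nrow(x), length(levels))
    sc[cbind(seq_len(nrow(x)), match(lab, levels))] <- 1
    return(sc)
  }
  sc <- matrix(0, nrow(x), length(levels))
  train_sq <- rowSums(fit$x^2)
  chunk <- max(1L, floor(2e7 / nrow(fit$x)))
  for (s in seq(1L, nrow(x), by = chunk)) {
    e <- min(nrow(x), s + chunk - 1L)
    xs <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xs^2), rep(1, nrow(fit$x))) - 2 * xs %*% t(fit$x) +
      outer(rep(1, nrow(xs)), train_sq)
    for (i in seq_len(nrow(xs))) {
      nb <- order(d2[i, ])[seq_len(k)]
      tab <- table(factor(fit$y[nb], levels = levels))
      sc[s + i - 1L, ] <- as.numeric(tab) / k
    }
  }
  sc
}

#' Score rows for new feature rows
#'
#' Every family emits one score row per input row: class posteriors for the
#' probabilistic families, and documented monotone surrogates (softmax of
#' negative centroid distances for MinDis, normalized likelihoods for
#' MaxLik, vote proportions for kNN) otherwise.  Rows are normalized to sum
#' to one; all entries lie in \[0, 1\].
#'
#' @param model A [fit_classifier()] result.
#' @param features Numeric matrix of rows to score.
#' @return An `n x n_levels` matrix with `colnames = model$levels`.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "callscore_model"))
  x <- pool_feature_rows(features)
  levels <- model$levels
  if (!is.null(model$constant)) {
    sc <- matrix(1, nrow(x), 1L, dimnames = list(NULL, levels))
    return(sc)
  }
  fit <- model$fit
  sc <- switch(model$spec$family,
    MinDis = min_distance_predict(x, fit)$scores,
    MaxLik = {
      lp <- predict_maxlik_log(fit, x)
      if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1L)
      softmax_rows(lp)
    },
    DecTr = predict(fit, data.frame(x), type = "prob"),
    kNN = predict_knn_scores(fit, x, levels),
    LogReg = {
      p <- predict(fit, data.frame(x), type = "probs")
      if (is.null(dim(p))) {
        if (length(levels) == 2L) p <- cbind(1 - p, p) else p <- matrix(p, nrow = 1L)
      }
      p
    },
    Neur = {
      p <- predict(fit, x)
      if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
      p
    },
    Discr = predict(fit, x)$posterior,
    Bayes = predict(fit, x, type = "raw")
  )
  sc <- as.matrix(sc)
  sc[!is.finite(sc)] <- 0
  sc <- pmax(sc, 0)
  rs <- rowSums(sc)
  zero <- rs <= 0
  if (any(zero)) {
    sc[zero, ] <- 1 / ncol(sc)
    rs[zero] <- 1
  }
  sc <- sc / rs
  colnames(sc) <- levels
  rownames(sc) <- NULL
  sc
}

#' Classify the frames of a recording into a score series
#'
#' Applies a trained frame classifier to a recording's normalized MFCC
#' features, yielding one score row and one label per frame.  Labels are
#' the row-wise argmax with the lowest class index winning ties.
#'
#' @param features Normalized feature matrix for one recording (rows in
#'   frame order), or a `frame_features` object already normalized.
#' @param model A [fit_classifier()] result (trained on the same
#'   normalizer and configuration).
#' @param hop_s Frame hop in seconds (taken from `features` if it is a
#'   `frame_features` object).
#' @return An object of class `score_series`: list with `scores`
#'   (`n_frames x n_levels`), `labels` (integer, 0 = silence/noise),
#'   `class_ids`, `hop_s`.
#' @export
classify_frames <- function(features, model, hop_s = NULL) {
  if (inherits(features, "frame_features") && is.null(hop_s)) {
    hop_s <- features$hop_s
  }
  if (is.null(hop_s)) stop("hop_s required")
  sc <- predict_scores(model, features)
  class_ids <- as.integer(model$levels)
  labels <- class_ids[max.col(sc, ties.method = "first")]
  structure(list(scores = sc, labels = labels, class_ids = class_ids,
                 hop_s = hop_s),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series> %d frames x %d classes (hop %.3f s)\n",
              nrow(x$scores), ncol(x$scores), x$hop_s))
  invisible(x)
}

#' Write a score series as CSV
#'
#' Header `t_s,s_class<id>...` with one row per frame.
#'
#' @param series A [classify_frames()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_series_csv <- function(series, path) {
  df <- data.frame(t_s = (seq_len(nrow(series$scores)) - 1L) * series$hop_s,
                   series$scores, check.names = FALSE)
  names(df)[-1L] <- paste0("s_class", series$class_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
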