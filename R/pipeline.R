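#' Rotating k-fold plan with train/validation/test roles
#'
#' Randomly permutes the recordings into k near-equal folds.  In iteration
#' `j` the test fold is `j`, the validation fold is `j + 1` (cyclically),
#' and the remaining `k - 2` folds train; after the full rotation every
#' recording has been used `k - 2` times for training, once for validation
#' and once for testing.
#'
#' @param n_recordings Number of recordings (or a vector of ids).
#' @param k Number of folds.
#' @param seed Permutation seed.
#' @param strata Optional per-recording stratum (e.g. class label); when
#'   given, recordings are dealt to folds round-robin within each stratum
#'   so fold class mixes stay balanced.  Off by default: the plain design
#'   is an unstratified random permutation.
#' @return An object of class `fold_plan`: list with `assignment`
#'   (per-recording fold index), `k`, `seed`.
#' @export
make_folds <- function(n_recordings, k = 7L, seed = 1L, strata = NULL) {
  n <- if (length(n_recordings) > 1L) length(n_recordings) else as.integer(n_recordings)
  k <- as.integer(k)
  if (n < k) stop_callscore("fewer recordings than folds", "callscore_invalid_input")
  assignment <- integer(n)
  if (is.null(strata)) {
    perm <- with_local_seed(seed, sample.int(n))
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    assignment[perm] <- rep(seq_len(k), times = sizes)
  } else {
    if (length(strata) != n) {
      stop_callscore("one stratum per recording required", "callscore_invalid_input")
    }
    with_local_seed(seed, {
      offset <- 0L
      for (s in unique(strata)) {
        idx <- which(strata == s)
        idx <- idx[sample.int(length(idx))]
        assignment[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- offset + length(idx)
      }
    })
  }
  structure(list(assignment = assignment, k = k, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Roles of every recording in one cross-validation iteration
#'
#' @param plan A [make_folds()] result.
#' @param iteration Iteration index in `1..k`.
#' @return A list with integer index vectors `train`, `validation`, `test`.
#' @export
fold_roles <- function(plan, iteration) {
  k <- plan$k
  test_fold <- ((iteration - 1L) %% k) + 1L
  val_fold <- (test_fold %% k) + 1L
  list(train = which(!plan$assignment %in% c(test_fold, val_fold)),
       validation = which(plan$assignment == val_fold),
       test = which(plan$assignment == test_fold))
}

#' Precompute MFCC features and frame ground truth for a dataset
#'
#' The per-recording feature matrices are deterministic, so they are
#' computed once and shared across folds and classifier sweeps.
#'
#' @param dataset List of [audio_recording()] objects (with ROIs).
#' @param config An [mfcc_config()].
#' @return A list with `features` (list of `frame_features`),
#'   `frame_labels` (list of integer vectors), `class_labels`, `hop_s`.
#' @export
precompute_features <- function(dataset, config = mfcc_config()) {
  features <- lapply(dataset, extract_mfcc, config = config)
  frame_labels <- lapply(dataset, label_frames, config = config)
  list(features = features, frame_labels = frame_labels,
       class_labels = vapply(dataset, function(r) r$class_label, integer(1)),
       hop_s = features[[1L]]$hop_s)
}

# Predicted label 0 marks an unclassifiable recording (all frames silent
# under counting).  The conservative scoring policy books it as an error
# against every class: it lands in the lowest-index wrong column.
resolve_unclassifiable <- function(truth, predicted, C) {
  bad <- predicted == 0L
  predicted[bad] <- ifelse(truth[bad] == 1L, 2L, 1L)
  predicted
}

#' Run the two-stage classification pipeline under cross-validation
#'
#' Per iteration: a feature normalizer and a frame classifier are fitted on
#' the training folds' ROI-labelled frames; every recording is converted to
#' a per-class score series; the recording label is then produced either by
#' frame counting or by a second-stage classifier trained on the training
#' folds' LFCC features (z-scored with training statistics).  Metrics are
#' computed on the test fold of each iteration and averaged.
#'
#' @param dataset List of [audio_recording()] objects.
#' @param plan A [make_folds()] plan over the same recordings.
#' @param frame_spec A [classifier_spec()] for the frame stage.
#' @param score_method `"counting"` or a [classifier_spec()] for the
#'   second stage.
#' @param mfcc_config,lfcc_config Stage configurations.
#' @param precomputed Optional [precompute_features()] result to share
#'   feature extraction across runs.
#' @param seed Seed for stochastic classifier trainers.
#' @return An object of class `two_stage_result`: list with
#'   `per_iteration` (`k x 10` metric matrix), `mean` (10-vector),
#'   `predictions` (data frame `recording`, `truth`, `predicted`,
#'   `iteration` pooled over test folds), `fit_ids` (per-iteration list of
#'   recording indices used in any fitting call), `frame_spec`,
#'   `score_method`.
#' @export
run_two_stage <- function(dataset, plan, frame_spec,
                          score_method = "counting",
                          mfcc_config = callscore::mfcc_config(),
                          lfcc_config = callscore::lfcc_config(),
                          precomputed = NULL, seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"))
  if (is.null(precomputed)) precomputed <- precompute_features(dataset, mfcc_config)
  counting <- identical(score_method, "counting")
  if (!counting) stopifnot(inherits(score_method, "classifier_spec"))
  class_labels <- precomputed$class_labels
  C <- max(class_labels)
  k <- plan$k
  per_iter <- matrix(NA_real_, k, 10L, dimnames = list(NULL, metric_names()))
  preds <- vector("list", k)
  fit_ids <- vector("list", k)
  for (it in seq_len(k)) {
    roles <- fold_roles(plan, it)
    fit_ids[[it]] <- roles$train
    train_x <- do.call(rbind, lapply(precomputed$features[roles$train],
                                     function(f) f$values))
    train_y <- factor(unlist(precomputed$frame_labels[roles$train]),
                      levels = 0:C)
    norm <- fit_normalizer(train_x)
    frame_model <- fit_classifier(apply_normalizer(train_x, norm),
                                  droplevels(train_y), frame_spec,
                                  seed = derive_seed(seed, it))
    series_for <- function(i) {
      classify_frames(apply_normalizer(precomputed$features[[i]]$values, norm),
                      frame_model, hop_s = precomputed$hop_s)
    }
    # LFCC over the full class set: classes unseen by the frame model get a
    # zero score series (their cepstral block is then identically zero).
    lfcc_for <- function(i) {
      s <- series_for(i)
      m <- matrix(0, nrow(s$scores), C)
      present <- s$class_ids[s$class_ids != 0L]
      m[, present] <- s$scores[, s$class_ids != 0L, drop = FALSE]
      lfcc(m, lfcc_config, hop_s = s$hop_s)
    }
    if (counting) {
      predicted <- vapply(roles$test, function(i) {
        tryCatch(count_classify(series_for(i)),
                 callscore_unclassifiable = function(e) 0L)
      }, integer(1))
    } else {
      train_lfcc <- t(vapply(roles$train, lfcc_for,
                             numeric(lfcc_config$n_ceps_kept * C)))
      norm2 <- fit_normalizer(train_lfcc)
      stage2 <- fit_classifier(apply_normalizer(train_lfcc, norm2),
                               droplevels(factor(class_labels[roles$train], levels = 1:C)),
                               score_method, seed = derive_seed(seed, 1000L + it))
      predicted <- vapply(roles$test, function(i) {
        v <- lfcc_for(i)
        score_classify(apply_normalizer(matrix(v, nrow = 1L), norm2), stage2)
      }, integer(1))
    }
    truth <- class_labels[roles$test]
    scored <- resolve_unclassifiable(truth, predicted, C)
    per_iter[it, ] <- global_metrics(confusion_matrix(truth, scored, C))
    preds[[it]] <- data.frame(recording = roles$test, truth = truth,
                              predicted = predicted, iteration = it)
  }
  structure(list(per_iteration = per_iter, mean = colMeans(per_iter),
                 predictions = do.call(rbind, preds), fit_ids = fit_ids,
                 frame_spec = frame_spec, score_method = score_method),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  sm <- if (identical(x$score_method, "counting")) "counting" else x$score_method$family
  cat(sprintf("<two_stage_result> %s frames -> %s (k = %d)\n",
              x$frame_spec$family, sm, nrow(x$per_iteration)))
  print(round(x$mean, 4))
  invisible(x)
}

#' Pooled test-fold predictions with the unclassifiable policy applied
#'
#' @param result A [run_two_stage()] result.
#' @param C Number of classes.
#' @return A data frame `recording`, `truth`, `predicted`, ordered by
#'   recording, one row per recording after the full rotation.
#' @export
pooled_predictions <- function(result, C = max(result$predictions$truth)) {
  p <- result$predictions
  p$predicted <- resolve_unclassifiable(p$truth, p$predicted, C)
  p[order(p$recording), c("recording", "truth", "predicted")]
}

#' Joint sweep of the (score method, frame classifier) grid
#'
#' Runs [run_two_stage()] for every combination of frame classifier family
#' and score method (frame counting plus the eight second-stage families),
#' reusing the MFCC features across all cells.  Individual cell failures
#' are recorded and the sweep continues.
#'
#' @param dataset List of [audio_recording()] objects.
#' @param plan A [make_folds()] plan.
#' @param frame_families Character vector of frame classifier families.
#' @param score_methods Character vector of score methods (`"counting"`
#'   and/or classifier families).
#' @param mfcc_config,lfcc_config Stage configurations.
#' @param seed Seed forwarded to every cell.
#' @return An object of class `grid_result`: list with `metrics` (a
#'   `score x frame x metric` array), `median_summary` (`score x frame`
#'   matrix of the median of the ten metrics), `improvement` (array of
#'   score-method metric minus counting metric, non-counting rows only),
#'   `errors` (list of failed cells).
#' @export
joint_grid <- function(dataset, plan,
                       frame_families = classifier_families(),
                       score_methods = c("counting", classifier_families()),
                       mfcc_config = callscore::mfcc_config(),
                       lfcc_config = callscore::lfcc_config(),
                       seed = 1L) {
  precomputed <- precompute_features(dataset, mfcc_config)
  metrics <- array(NA_real_,
                   dim = c(length(score_methods), length(frame_families), 10L),
                   dimnames = list(score_methods, frame_families, metric_names()))
  errors <- list()
  for (fi in seq_along(frame_families)) {
    for (si in seq_along(score_methods)) {
      sm <- score_methods[si]
      method <- if (identical(sm, "counting")) "counting" else classifier_spec(sm)
      res <- tryCatch(
        run_two_stage(dataset, plan, classifier_spec(frame_families[fi]),
                      method, mfcc_config, lfcc_config,
                      precomputed = precomputed, seed = seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(sm, frame_families[fi], sep = "-")]] <- conditionMessage(res)
      } else {
        metrics[si, fi, ] <- res$mean
      }
    }
  }
  median_summary <- apply(metrics, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v)
  })
  improvement <- NULL
  if ("counting" %in% score_methods) {
    counting_row <- metrics["counting", , , drop = FALSE]
    others <- setdiff(score_methods, "counting")
    improvement <- metrics[others, , , drop = FALSE] -
      counting_row[rep(1L, length(others)), , , drop = FALSE]
  }
  structure(list(metrics = metrics, median_summary = median_summary,
                 improvement = improvement, errors = errors),
            class = "grid_result")
}

#' Grid tensor in long format
#'
#' @param grid A [joint_grid()] result.
#' @return A data frame `score_method,frame_method,metric,value`.
#' @export
grid_long <- function(grid) {
  dn <- dimnames(grid$metrics)
  expand <- expand.grid(score_method = dn[[1L]], frame_method = dn[[2L]],
                        metric = dn[[3L]], stringsAsFactors = FALSE)
  expand$value <- as.vector(grid$metrics)
  expand
}
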