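test_that("the z-score normalizer matches its definition", {
  set.seed(7)
  x <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4)
  nm <- fit_normalizer(x)
  expect_equal(nm$mu, colMeans(x), tolerance = 1e-12)
  expect_equal(nm$sigma, apply(x, 2, sd), tolerance = 1e-12)

  two <- fit_normalizer(matrix(c(1, 3), 2, 1))
  expect_equal(two$mu, 2)
  expect_equal(two$sigma, sqrt(2))   # sample (n-1) convention

  z <- apply_normalizer(x, nm)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)

  pre <- scale(x)
  attr(pre, "scaled:center") <- NULL; attr(pre, "scaled:scale") <- NULL
  nm2 <- fit_normalizer(matrix(as.numeric(pre), nrow(pre)))
  expect_lt(max(abs(nm2$mu)), 1e-12)
  expect_lt(max(abs(nm2$sigma - 1)), 1e-12)

  expect_equal(apply_normalizer(matrix(5, 1, 1),
                                structure(list(mu = 3, sigma = 2),
                                          class = "feature_normalizer"))[1, 1], 1)
  expect_error(fit_normalizer(matrix(1, 1, 3)), class = "callscore_invalid_input")
  expect_error(apply_normalizer(matrix(1, 2, 2), nm),
               class = "callscore_invalid_input")

  # constant features are floored, not NaN
  flo <- fit_normalizer(matrix(c(1, 1, 1, 2, 3, 4), 3, 2))
  expect_equal(flo$sigma[1], 1e-8)
  expect_true(all(is.finite(apply_normalizer(matrix(1, 1, 2), flo))))
})

test_that("minimum-distance training recovers per-class centroids", {
  x <- rbind(c(0, 0), c(2, 2), c(5, 5))
  m <- min_distance_train(x, c(0, 0, 1))
  expect_equal(unname(m$centroids[1, ]), c(1, 1))
  expect_equal(unname(m$centroids[2, ]), c(5, 5))

  one_each <- min_distance_train(rbind(c(1, 2), c(3, 4)), c(1, 2))
  expect_equal(unname(one_each$centroids), rbind(c(1, 2), c(3, 4)))

  set.seed(15)
  xr <- matrix(rnorm(300), 100, 3)
  yr <- sample(0:2, 100, TRUE)
  mr <- min_distance_train(xr, yr)
  for (l in 0:2) {
    expect_equal(unname(mr$centroids[as.character(l) == mr$levels, ]),
                 colMeans(xr[yr == l, , drop = FALSE]), tolerance = 1e-12)
  }
  expect_error(min_distance_train(xr[yr != 2, ], factor(yr[yr != 2], levels = 0:2)),
               class = "callscore_missing_class")
})

test_that("minimum-distance prediction is an exhaustive nearest-centroid search", {
  m <- min_distance_train(rbind(c(3, 4), c(-3, -4)), c(1, 2))
  p <- min_distance_predict(matrix(c(0, 0), 1), m)
  expect_equal(p$distances[1, ], c(5, 5), ignore_attr = TRUE)  # 3-4-5
  expect_identical(p$labels, "1")                              # lowest-index tie

  p2 <- min_distance_predict(matrix(c(3, 4), 1), m)
  expect_equal(p2$distances[1, 1], 0, ignore_attr = TRUE)
  expect_identical(p2$labels, "1")

  set.seed(23)
  xr <- matrix(rnorm(500), 100, 5)
  centroids <- matrix(rnorm(20), 4, 5)
  model <- structure(list(centroids = centroids, levels = as.character(1:4)),
                     class = "centroid_model")
  got <- min_distance_predict(xr, model)
  expect_identical(got$labels, as.character(oracle_min_distance(xr, centroids)))
  expect_equal(rowSums(got$scores), rep(1, 100), tolerance = 1e-9)
})

test_that("every classifier family honours the score-series contract", {
  blobs <- make_blobs(rbind(c(0, 0), c(4, 0), c(0, 4)), n_per = 40, seed = 31)
  test <- make_blobs(rbind(c(0, 0), c(4, 0), c(0, 4)), n_per = 15, seed = 32)
  for (family in classifier_families()) {
    model <- fit_classifier(blobs$x, blobs$y, classifier_spec(family), seed = 5)
    sc <- predict_scores(model, test$x)
    expect_identical(dim(sc), c(45L, 3L))
    expect_true(all(sc >= 0 & sc <= 1), label = paste(family, "range"))
    expect_equal(rowSums(sc), rep(1, 45), tolerance = 1e-6)

    series <- classify_frames(test$x, model, hop_s = 0.01)
    expect_identical(series$labels,
                     series$class_ids[max.col(series$scores, ties.method = "first")])
    acc <- mean(series$labels == test$y)
    expect_gt(acc, 0.9)
  }
})

test_that("a 4-call-class frame problem yields 5 score columns", {
  blobs <- make_blobs(rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3), c(6, 6)),
                      n_per = 12, seed = 41)
  model <- fit_classifier(blobs$x, blobs$y, classifier_spec("MinDis"))
  series <- classify_frames(blobs$x, model, hop_s = 0.01)
  expect_identical(ncol(series$scores), 5L)
  expect_identical(series$class_ids, 0:4)
})

test_that("kNN is exact on separable data and emits vote proportions", {
  blobs <- make_blobs(rbind(c(0, 0), c(10, 10)), n_per = 25, seed = 51)
  model <- fit_classifier(blobs$x, blobs$y, classifier_spec("kNN"))
  series <- classify_frames(blobs$x, model, hop_s = 0.01)
  expect_identical(series$labels, as.integer(blobs$y))

  model3 <- fit_classifier(blobs$x, blobs$y, classifier_spec("kNN", k = 3))
  sc <- predict_scores(model3, blobs$x)
  expect_true(all(abs(sc * 3 - round(sc * 3)) < 1e-9))
  expect_equal(rowSums(sc), rep(1, 50), tolerance = 1e-9)
})

test_that("degenerate one-class training yields the constant classifier", {
  x <- matrix(rnorm(20), 10, 2)
  model <- fit_classifier(x, rep(2L, 10), classifier_spec("DecTr"))
  sc <- predict_scores(model, x)
  expect_true(all(sc == 1))
  expect_identical(colnames(sc), "2")
})

test_that("Gaussian likelihood boundary converges to the analytic threshold", {
  set.seed(61)
  n <- 4000
  x <- matrix(c(rnorm(n, 0, 1), rnorm(n, 2, 1)), ncol = 1)
  y <- rep(1:2, each = n)
  model <- fit_classifier(x, y, classifier_spec("MaxLik", gmm_components = 1))
  grid <- matrix(seq(0.5, 1.5, by = 0.001), ncol = 1)
  sc <- predict_scores(model, grid)
  boundary <- grid[which(sc[, 2] > sc[, 1])[1], 1]
  expect_lt(abs(boundary - 1), 3 / sqrt(n))
})
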