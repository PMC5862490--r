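train_table <- function(sd = 0.01, seed = 41, n_per = 9) {
  meas <- fake_measurements(
    n_per = n_per,
    conditions = c("tca_inhibition", "etc_inhibition", "oxphos_uncoupling"),
    sd = sd, seed = seed)
  build_feature_table(meas, harmonic = 1)
}

test_that("feature tables carry 3 features, exclude glycolysis, and validate", {
  meas <- fake_measurements(conditions = c("baseline", "glycolysis_inhibition",
                                           "tca_inhibition", "etc_inhibition",
                                           "oxphos_uncoupling"))
  expect_message(ft <- build_feature_table(meas, 1), "excluding")
  expect_equal(nrow(ft), 27L)  # 3 classes x 9 measurements
  expect_equal(sort(unique(ft$class)), c("ETC", "OXPHOS", "TCA"))
  expect_named(ft, c("g", "s", "delta_I", "class"))

  odd <- rbind(meas, transform(meas[1, ], condition = "mystery"))
  expect_error(suppressMessages(build_feature_table(odd, 1)), "unmapped")
  expect_error(build_feature_table(meas[0, ], 1), "no measurements")

  test_ft <- build_feature_table(meas, 1, class_map = NULL)
  expect_equal(nrow(test_ft), nrow(meas))  # nothing excluded for test tables
})

test_that("well-separated clusters are classified perfectly by all algorithms", {
  ft <- train_table(sd = 0.005)
  for (algo in c("lda", "knn", "nb")) {
    model <- train_classifier(ft, algo)
    pred <- flimphasor:::.predict_labels(model, flimphasor:::.feature_matrix(ft))
    expect_equal(pred, ft$class, info = algo)
  }
  expect_error(train_classifier(ft[ft$class == "ETC", ], "lda"), "2 classes")
})

test_that("naive Bayes posteriors match hand-computed Gaussian Bayes on 4 points", {
  ft <- structure(
    data.frame(g = c(0.1, 0.2, 0.8, 1.0), s = c(0.4, 0.5, 0.1, 0.2),
               delta_I = c(0.0, 0.1, 0.6, 0.8),
               class = c("A", "A", "B", "B"), stringsAsFactors = FALSE),
    harmonic = 1L, known_class = TRUE,
    class = c("flim_features", "data.frame"))
  model <- train_classifier(ft, "nb")
  x <- c(g = 0.3, s = 0.35, delta_I = 0.2)
  post <- stats::predict(model$fit,
                         as.data.frame(t(x)), type = "raw")
  lik <- function(cls) {
    rows <- ft[ft$class == cls, 1:3]
    prod(vapply(1:3, function(j)
      dnorm(x[j], mean(rows[[j]]), sd(rows[[j]])), 1))
  }
  pa <- 0.5 * lik("A"); pb <- 0.5 * lik("B")
  expect_equal(unname(post[1, "A"]), pa / (pa + pb), tolerance = 1e-9)
  expect_equal(unname(post[1, "B"]), pb / (pa + pb), tolerance = 1e-9)
})

test_that("LDA with identical class means scores classes by their priors", {
  set.seed(51)
  noise <- matrix(rnorm(60, sd = 0.1), 20, 3)
  ft <- structure(
    data.frame(g = noise[, 1], s = noise[, 2], delta_I = noise[, 3],
               class = rep(c("A", "B"), each = 10), stringsAsFactors = FALSE),
    harmonic = 1L, known_class = TRUE,
    class = c("flim_features", "data.frame"))
  # force exactly identical class means
  for (j in 1:3) {
    ft[ft$class == "B", j] <- ft[ft$class == "B", j] -
      mean(ft[ft$class == "B", j]) + mean(ft[ft$class == "A", j])
  }
  model <- train_classifier(ft, "lda")
  mu <- colMeans(flimphasor:::.feature_matrix(ft))
  post <- stats::predict(model$fit, t(mu))$posterior
  expect_equal(unname(post[1, "A"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(post[1, "B"]), 0.5, tolerance = 1e-9)
})

test_that("cross-validation is exact on separated clusters and matches manual LOO", {
  ft <- train_table(sd = 0.005)
  expect_equal(as.numeric(kfold_cv_error(ft, "lda", K = 5, seed = 2)), 0)
  expect_equal(as.numeric(kfold_cv_error(ft, "knn", K = 5, seed = 2)), 0)

  ftn <- train_table(sd = 0.08, seed = 43)  # overlapping clusters
  loo <- kfold_cv_error(ftn, "nb", K = nrow(ftn))
  manual <- mean(vapply(seq_len(nrow(ftn)), function(i) {
    sub <- ftn[-i, , drop = FALSE]
    attr(sub, "harmonic") <- 1L
    class(sub) <- c("flim_features", "data.frame")
    model <- train_classifier(sub, "nb")
    pred <- flimphasor:::.predict_labels(
      model, flimphasor:::.feature_matrix(ftn[i, , drop = FALSE]))
    pred != ftn$class[i]
  }, logical(1)))
  expect_equal(as.numeric(loo), manual)

  expect_error(kfold_cv_error(ft[ft$class == "ETC", ], "lda", K = 3),
               "single class")
  expect_error(kfold_cv_error(ft, "lda", K = 100), "between 2")
})

test_that("cross-validation error is invariant to row order given the seed", {
  ft <- train_table(sd = 0.08, seed = 44)
  e1 <- as.numeric(kfold_cv_error(ft, "knn", K = 5, seed = 9))
  set.seed(1000)
  perm <- sample.int(nrow(ft))
  ftp <- ft[perm, , drop = FALSE]
  attr(ftp, "harmonic") <- 1L
  class(ftp) <- c("flim_features", "data.frame")
  e2 <- as.numeric(kfold_cv_error(ftp, "knn", K = 5, seed = 9))
  expect_equal(e1, e2)
})

test_that("prediction honors centroids, nearest neighbors, and the tie-break", {
  ft <- train_table(sd = 0.005)
  model <- train_classifier(ft, "lda")
  centroid <- colMeans(flimphasor:::.feature_matrix(ft[ft$class == "ETC", ]))
  lab <- flimphasor:::.predict_labels(model, t(centroid))
  expect_equal(lab, "ETC")

  knn1 <- train_classifier(ft, "knn", knn_k = 1)
  lab1 <- flimphasor:::.predict_labels(
    knn1, flimphasor:::.feature_matrix(ft[5, , drop = FALSE]))
  expect_equal(lab1, ft$class[5])

  # 2 neighbors from different classes tie; the smaller label must win
  tie <- structure(
    data.frame(g = c(0, 1, 0, 1), s = c(0, 1, 0, 1), delta_I = c(0, 1, 0, 1),
               class = c("B", "A", "B", "A"), stringsAsFactors = FALSE),
    harmonic = 1L, known_class = TRUE,
    class = c("flim_features", "data.frame"))
  knn2 <- train_classifier(tie, "knn", knn_k = 2)
  lab2 <- flimphasor:::.predict_labels(knn2, matrix(c(0.5, 0.5, 0.5), 1))
  expect_equal(lab2, "A")

  pred <- predict(model, fake_measurements(conditions = "etc_inhibition",
                                           sd = 0.005, seed = 77))
  expect_equal(unname(pred$fractions["ETC"]), 1)
  expect_equal(sum(pred$fractions), 1)
})

test_that("LDA decision boundaries are affine: equal-prior midpoints score equally", {
  set.seed(61)
  a <- matrix(rnorm(30, 0, 0.2), 10, 3)
  b <- sweep(matrix(rnorm(30, 0, 0.2), 10, 3), 2, c(1, 1, 1), "+")
  ft <- structure(
    data.frame(g = c(a[, 1], b[, 1]), s = c(a[, 2], b[, 2]),
               delta_I = c(a[, 3], b[, 3]),
               class = rep(c("A", "B"), each = 10), stringsAsFactors = FALSE),
    harmonic = 1L, known_class = TRUE,
    class = c("flim_features", "data.frame"))
  model <- train_classifier(ft, "lda")
  mid <- (colMeans(flimphasor:::.feature_matrix(ft)[1:10, ]) +
          colMeans(flimphasor:::.feature_matrix(ft)[11:20, ])) / 2
  post <- stats::predict(model$fit, t(mid))$posterior
  expect_equal(unname(post[1, "A"]), unname(post[1, "B"]), tolerance = 1e-9)
})
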