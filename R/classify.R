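# Classification of metabolic disruptions in the 3-feature space
# (g, s, delta_I): LDA, KNN and Gaussian naive Bayes, with stratified
# K-fold cross-validation.

#' Default condition-to-class mapping
#'
#' Mitochondrial conditions map to their process class; baseline and
#' glycolysis inhibition are excluded from training (glycolysis does not
#' separate from baseline, so it carries no class signal).
#'
#' @return Named character vector `condition -> class`.
#' @export
default_class_map <- function() {
  c(tca_inhibition = "TCA", etc_inhibition = "ETC",
    oxphos_uncoupling = "OXPHOS")
}

#' Build the 3-feature table for classification
#'
#' One row per measurement with features `g`, `s` (at the chosen harmonic)
#' and `delta_I`, plus the class label from `class_map`. Conditions listed in
#' `exclude` are dropped (with a message); any other unmapped condition is an
#' error. With `class_map = NULL` all conditions are kept and the class
#' column is the raw condition label with `known_class = FALSE` -- the form
#' used for held-out test measurements.
#'
#' @param measurements Measurement data.frame (see [measurement_table()]) or
#'   list of [measurement_point()]s.
#' @param harmonic Harmonic whose `g`/`s` columns feed the features.
#' @param class_map Named character vector `condition -> class`, or `NULL`.
#' @param exclude Conditions silently dropped under the default map.
#' @return data.frame of class `flim_features` with columns `g`, `s`,
#'   `delta_I`, `class` and attribute `harmonic`.
#' @export
build_feature_table <- function(measurements, harmonic = 1L,
                                class_map = default_class_map(),
                                exclude = c("baseline", "glycolysis_inhibition")) {
  if (!is.data.frame(measurements)) measurements <- measurement_table(measurements)
  if (nrow(measurements) == 0L) stop("no measurements", call. = FALSE)
  gcol <- paste0("g", harmonic); scol <- paste0("s", harmonic)
  if (!all(c(gcol, scol) %in% names(measurements)))
    stop(sprintf("measurement table lacks harmonic %d columns", harmonic),
         call. = FALSE)
  if (is.null(class_map)) {
    tab <- data.frame(g = measurements[[gcol]], s = measurements[[scol]],
                      delta_I = measurements$delta_intensity,
                      class = measurements$condition,
                      stringsAsFactors = FALSE)
  } else {
    drop <- measurements$condition %in% exclude
    if (any(drop))
      message(sprintf("excluding %d measurement(s) from condition(s): %s",
                      sum(drop),
                      paste(unique(measurements$condition[drop]), collapse = ", ")))
    measurements <- measurements[!drop, , drop = FALSE]
    unmapped <- setdiff(unique(measurements$condition), names(class_map))
    if (length(unmapped))
      stop("unmapped condition(s): ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    if (nrow(measurements) == 0L)
      stop("no measurements remain after exclusion", call. = FALSE)
    tab <- data.frame(g = measurements[[gcol]], s = measurements[[scol]],
                      delta_I = measurements$delta_intensity,
                      class = unname(class_map[measurements$condition]),
                      stringsAsFactors = FALSE)
  }
  if (anyNA(tab)) stop("feature table contains missing values", call. = FALSE)
  structure(tab, harmonic = as.integer(harmonic),
            known_class = !is.null(class_map),
            class = c("flim_features", "data.frame"))
}

.feature_matrix <- function(table) {
  as.matrix(table[, c("g", "s", "delta_I")])
}

#' Train a classifier on a feature table
#'
#' * `"lda"`: linear discriminant analysis with shared pooled within-class
#'   covariance and empirical class priors (via \pkg{MASS}).
#' * `"knn"`: K-nearest neighbors on per-feature z-scored features (scaling
#'   fitted on the training data; required because `delta_I` and the phasor
#'   coordinates differ in magnitude). Ties are broken deterministically in
#'   favor of the alphabetically smallest class label.
#' * `"nb"`: Gaussian naive Bayes with empirical priors (via \pkg{e1071}); a
#'   variance floor of 1e-12 is applied to fitted per-class standard
#'   deviations (with a message) so degenerate inputs survive.
#'
#' @param table A [build_feature_table()] result with at least 2 classes.
#' @param algo `"lda"`, `"knn"` or `"nb"`.
#' @param knn_k Neighbor count for KNN (odd values avoid binary ties).
#' @param var_floor Variance floor for naive Bayes.
#' @return An object of class `flim_classifier`.
#' @export
train_classifier <- function(table, algo = c("lda", "knn", "nb"),
                             knn_k = 3L, var_floor = 1e-12) {
  algo <- match.arg(algo)
  stopifnot(inherits(table, "flim_features"))
  cls <- factor(table$class)
  if (nlevels(cls) < 2L)
    stop("training requires at least 2 classes", call. = FALSE)
  X <- .feature_matrix(table)
  model <- list(algo = algo, classes = levels(cls),
                harmonic = attr(table, "harmonic"))
  if (algo == "lda") {
    fit <- tryCatch(MASS::lda(x = X, grouping = cls),
                    error = function(e)
                      stop("LDA failed (singular pooled covariance?): ",
                           conditionMessage(e), call. = FALSE))
    model$fit <- fit
  } else if (algo == "nb") {
    fit <- e1071::naiveBayes(x = as.data.frame(X), y = cls)
    floored <- FALSE
    for (v in names(fit$tables)) {
      sd_v <- fit$tables[[v]][, 2]
      low <- !is.finite(sd_v) | sd_v < sqrt(var_floor)
      if (any(low)) {
        fit$tables[[v]][low, 2] <- sqrt(var_floor)
        floored <- TRUE
      }
    }
    if (floored)
      message("naive Bayes: variance floor applied to degenerate class(es)")
    model$fit <- fit
  } else {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    model$scaling <- list(center = mu, scale = sdv)
    model$train_x <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    model$train_y <- cls
    model$knn_k <- as.integer(knn_k)
  }
  class(model) <- "flim_classifier"
  model
}

#' @export
print.flim_classifier <- function(x, ...) {
  cat(sprintf("%s classifier on (g, s, delta_I), harmonic %d, classes: %s\n",
              toupper(x$algo), x$harmonic, paste(x$classes, collapse = ", ")))
  invisible(x)
}

.predict_labels <- function(model, X) {
  if (model$algo == "lda") {
    as.character(stats::predict(model$fit, X)$class)
  } else if (model$algo == "nb") {
    post <- stats::predict(model$fit, as.data.frame(X), type = "raw")
    model$classes[max.col(post, ties.method = "first")]
  } else {
    Z <- sweep(sweep(X, 2, model$scaling$center), 2, model$scaling$scale, "/")
    k <- min(model$knn_k, nrow(model$train_x))
    unname(apply(Z, 1, function(z) {
      d2 <- colSums((t(model$train_x) - z)^2)
      nn <- model$train_y[order(d2)[seq_len(k)]]
      votes <- table(nn)
      # deterministic tie-break: smallest class label among tied votes
      names(votes)[which.max(votes)]
    }))
  }
}

#' Predict metabolic classes for measurements
#'
#' @param object A trained [train_classifier()] model.
#' @param newdata A `flim_features` table, a measurement data.frame, or a
#'   list of [measurement_point()]s (features are extracted at the model's
#'   harmonic).
#' @param ... Unused.
#' @return An object of class `flim_prediction`: per-measurement `labels` and
#'   the summary `fractions` assigned to each class.
#' @export
predict.flim_classifier <- function(object, newdata, ...) {
  if (!inherits(newdata, "flim_features"))
    newdata <- build_feature_table(newdata, harmonic = object$harmonic,
                                   class_map = NULL)
  X <- .feature_matrix(newdata)
  labels <- .predict_labels(object, X)
  fr <- table(factor(labels, levels = object$classes)) / length(labels)
  structure(list(labels = labels,
                 fractions = stats::setNames(as.numeric(fr), object$classes),
                 algo = object$algo, n = length(labels)),
            class = "flim_prediction")
}

#' @export
print.flim_prediction <- function(x, ...) {
  cat(sprintf("%s prediction over %d measurement(s):\n", toupper(x$algo), x$n))
  for (cl in names(x$fractions))
    cat(sprintf("  %-8s %5.1f%%\n", cl, 100 * x$fractions[cl]))
  invisible(x)
}

# Canonical row order (class, then features) so fold assignment depends only
# on the data values, never on the incoming row order.
.canonical_order <- function(table) {
  order(table$class, table$g, table$s, table$delta_I)
}

#' Stratified K-fold cross-validation error
#'
#' Rows are put in a canonical order (class, then feature values), shuffled
#' within class under `seed`, and dealt round-robin into `K` stratified
#' folds; each fold is predicted by a model trained on the remaining folds.
#' `K = n` is exact leave-one-out with a seed-free assignment. The returned
#' error is the mean misclassification fraction (1 - error is the accuracy).
#'
#' @param table A [build_feature_table()] result.
#' @param algo,knn_k,var_floor As in [train_classifier()].
#' @param K Number of folds, between 2 and `n`.
#' @param seed Integer seed for the stratified shuffle.
#' @return Misclassification rate in `[0, 1]`, with attribute `"folds"`.
#' @export
kfold_cv_error <- function(table, algo = c("lda", "knn", "nb"), K = 5L,
                           seed = 1L, knn_k = 3L, var_floor = 1e-12) {
  algo <- match.arg(algo)
  stopifnot(inherits(table, "flim_features"))
  n <- nrow(table)
  K <- as.integer(K)
  if (is.na(K) || K < 2L || K > n)
    stop("'K' must lie between 2 and the number of rows", call. = FALSE)
  if (length(unique(table$class)) < 2L)
    stop("cross-validation undefined for a single class", call. = FALSE)
  ord <- .canonical_order(table)
  folds <- integer(n)
  if (K == n) {
    folds[ord] <- seq_len(n)  # leave-one-out, seed-free
  } else {
    set.seed(seed)
    for (cl in sort(unique(table$class))) {
      idx <- ord[table$class[ord] == cl]
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(K), length(idx))
    }
  }
  wrong <- 0L
  for (f in sort(unique(folds))) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    if (length(unique(table$class[train_idx])) < 2L)
      stop(sprintf("fold %d leaves fewer than 2 classes for training", f),
           call. = FALSE)
    sub <- table[train_idx, , drop = FALSE]
    attr(sub, "harmonic") <- attr(table, "harmonic")
    class(sub) <- c("flim_features", "data.frame")
    model <- train_classifier(sub, algo, knn_k = knn_k, var_floor = var_floor)
    pred <- .predict_labels(model, .feature_matrix(table[test_idx, , drop = FALSE]))
    wrong <- wrong + sum(pred != table$class[test_idx])
  }
  structure(wrong / n, folds = folds)
}
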