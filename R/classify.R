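#' The ten benchmarked classifier configurations
#'
#' Registry of the classifier settings compared by the pipeline, with
#' hyperparameters pinned to the benchmarked values: AdaBoost (SAMME.R,
#' 600 depth-5 trees, learning rate 50 -- far outside typical ranges but
#' kept as benchmarked), an unpruned gini decision tree, Gaussian naive
#' Bayes, 5-nearest-neighbours, a single-hidden-layer perceptron (100
#' units, weight decay 2), quadratic discriminant analysis, random forests
#' with entropy (balanced class weights) and gini criteria (100 depth-5
#' trees), and support vector machines with linear and RBF kernels
#' (`C = 1`, `gamma = 1.5`; gamma is inert for the linear kernel).
#'
#' @return character vector of the 10 registry names.
#' @export
classifier_names <- function() {
  c("adaboost", "decision_tree", "gnb", "knn", "mlp", "qda",
    "rf_entropy", "rf_gini", "svm_linear", "svm_rbf")
}

#' Construct a classifier specification
#'
#' @param name one of [classifier_names()].
#' @param seed integer seed applied before every stochastic fit so that two
#'   fits on the same data give identical predictions.
#' @param params named list of hyperparameter overrides (defaults are the
#'   pinned registry values).
#' @return object of class `classifier_spec`.
#' @export
make_classifier <- function(name, seed = 1L, params = list()) {
  if (!name %in% classifier_names()) {
    stop(sprintf("unknown classifier '%s'; valid names: %s", name,
                 paste(classifier_names(), collapse = ", ")), call. = FALSE)
  }
  defaults <- switch(name,
    adaboost = list(n_estimators = 600L, learning_rate = 50, max_depth = 5L),
    decision_tree = list(max_depth = 30L),
    gnb = list(),
    knn = list(k = 5L),
    mlp = list(size = 100L, decay = 2, maxit = 200L),
    qda = list(),
    rf_entropy = list(n_trees = 100L, max_depth = 5L, split = "information",
                      balanced = TRUE),
    rf_gini = list(n_trees = 100L, max_depth = 5L, split = "gini",
                   balanced = FALSE),
    svm_linear = list(cost = 1, gamma = 1.5, kernel = "linear"),
    svm_rbf = list(cost = 1, gamma = 1.5, kernel = "radial"))
  defaults[names(params)] <- params
  structure(list(name = name, seed = as.integer(seed), params = defaults),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("classifier_spec '%s' (seed %d)\n", x$name, x$seed))
  if (length(x$params)) utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Fit a classifier on training data and predict test labels
#'
#' Uniform train/predict contract over the registry. Predictions are drawn
#' from the training label set; a degenerate single-class training set
#' yields constant predictions of that class.
#'
#' @param spec a [make_classifier()] specification.
#' @param x_train,x_test numeric matrices (or data.frames) with matching
#'   columns.
#' @param y_train factor (or coercible) of training labels.
#' @return factor of predicted labels, levels = training levels.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test) {
  stopifnot(inherits(spec, "classifier_spec"))
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  if (ncol(x_train) != ncol(x_test)) {
    stop("train and test feature dimensions differ", call. = FALSE)
  }
  colnames(x_train) <- colnames(x_test) <- paste0("f", seq_len(ncol(x_train)))
  y <- factor(y_train)
  if (nlevels(y) < 2L) {
    return(factor(rep(levels(y)[1], nrow(x_test)), levels = levels(y)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  p <- spec$params
  pred <- switch(spec$name,
    knn = class::knn(x_train, x_test, cl = y, k = p$k),
    decision_tree = {
      df <- data.frame(.y = y, x_train)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            minsplit = 2L, minbucket = 1L, cp = 0,
                            maxdepth = p$max_depth, xval = 0L))
      .rpart_class(fit, x_test)
    },
    gnb = {
      fit <- e1071::naiveBayes(x_train, y)
      stats::predict(fit, as.data.frame(x_test))
    },
    qda = {
      fit <- MASS::qda(x_train, grouping = y)
      stats::predict(fit, x_test)$class
    },
    mlp = {
      fit <- nnet::nnet(x_train, nnet::class.ind(y), size = p$size,
                        decay = p$decay, maxit = p$maxit, softmax = TRUE,
                        MaxNWts = 100000L, trace = FALSE)
      pr <- stats::predict(fit, x_test)
      factor(levels(y)[max.col(pr)], levels = levels(y))
    },
    svm_linear = ,
    svm_rbf = {
      fit <- e1071::svm(x_train, y, type = "C-classification",
                        kernel = p$kernel, cost = p$cost, gamma = p$gamma,
                        scale = FALSE)
      stats::predict(fit, x_test)
    },
    rf_entropy = ,
    rf_gini = .forest_fit_predict(x_train, y, x_test, n_trees = p$n_trees,
                                  max_depth = p$max_depth, split = p$split,
                                  balanced = p$balanced),
    adaboost = .adaboost_fit_predict(x_train, y, x_test,
                                     n_estimators = p$n_estimators,
                                     learning_rate = p$learning_rate,
                                     max_depth = p$max_depth))
  factor(as.character(pred), levels = levels(y))
}

.rpart_class <- function(fit, x_test) {
  pr <- stats::predict(fit, data.frame(x_test), type = "class")
  pr
}

# Bagged-tree random forest: bootstrap rows, `mtry = floor(sqrt(p))`
# feature subsampling, depth-capped CART trees with the requested impurity
# criterion, majority vote. The single code path keeps the gini-vs-entropy
# registry pair a pure criterion contrast.
.forest_fit_predict <- function(x, y, x_test, n_trees, max_depth, split,
                                balanced) {
  n <- nrow(x)
  pfeat <- ncol(x)
  mtry <- min(pfeat, max(2L, floor(sqrt(pfeat))))
  lev <- levels(y)
  w <- if (balanced) {
    tab <- table(y)
    (n / (length(tab) * as.numeric(tab)))[as.integer(y)]
  } else rep(1, n)
  votes <- matrix(0L, nrow = nrow(x_test), ncol = length(lev))
  ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                               maxdepth = max_depth, xval = 0L)
  for (t in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    cols <- sample.int(pfeat, mtry)
    df <- data.frame(.y = y[rows], x[rows, cols, drop = FALSE])
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        weights = w[rows], parms = list(split = split),
                        control = ctrl)
    pr <- stats::predict(fit, data.frame(x_test[, cols, drop = FALSE]),
                         type = "class")
    idx <- cbind(seq_len(nrow(x_test)), match(as.character(pr), lev))
    votes[idx] <- votes[idx] + 1L
  }
  factor(lev[max.col(votes, ties.method = "first")], levels = lev)
}

# Multiclass real-valued (SAMME.R-style) adaptive boosting with depth-
# capped CART base learners. The additive decision function accumulates
# (K-1) * (log p_k - mean log p); the learning rate enters the exponential
# weight update, with log-space normalization so that even the benchmarked
# extreme rate of 50 stays finite.
.adaboost_fit_predict <- function(x, y, x_test, n_estimators, learning_rate,
                                  max_depth) {
  n <- nrow(x)
  K <- nlevels(y)
  lev <- levels(y)
  Y <- matrix(-1 / (K - 1), nrow = n, ncol = K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  w <- rep(1 / n, n)
  Fdec <- matrix(0, nrow = nrow(x_test), ncol = K)
  ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                               maxdepth = max_depth, xval = 0L)
  eps <- .Machine$double.eps
  df_all <- data.frame(x)
  df_test <- data.frame(x_test)
  colnames(df_test) <- colnames(df_all)
  for (t in seq_len(n_estimators)) {
    df <- cbind(.y = y, df_all)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class", weights = w * n,
                        parms = list(split = "gini"), control = ctrl)
    ptr <- stats::predict(fit, df_all, type = "prob")
    ptr <- pmax(ptr, eps)
    logp <- log(ptr)
    pte <- pmax(stats::predict(fit, df_test, type = "prob"), eps)
    logpte <- log(pte)
    Fdec <- Fdec + (K - 1) * (logpte - rowMeans(logpte))
    logw <- log(w) - learning_rate * ((K - 1) / K) * rowSums(Y * logp)
    logw <- logw - max(logw)
    w <- exp(logw)
    s <- sum(w)
    if (!is.finite(s) || s <= 0) break
    w <- w / s
  }
  factor(lev[max.col(Fdec, ties.method = "first")], levels = lev)
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true,pred equal-length label vectors (factors with common levels,
#'   or integers in `0 .. n_class-1`).
#' @param n_class number of classes (used for integer labels).
#' @return `n_class x n_class` count matrix; entry (i, j) counts true class
#'   i predicted as class j, so row sums are the per-class test counts.
#' @export
confusion_matrix <- function(true, pred, n_class = 3L) {
  if (length(true) != length(pred)) {
    stop("`true` and `pred` must have equal length", call. = FALSE)
  }
  if (is.factor(true) || is.factor(pred)) {
    lev <- levels(factor(true, levels = union(levels(factor(true)),
                                              levels(factor(pred)))))
    true <- factor(as.character(true), levels = lev)
    pred <- factor(as.character(pred), levels = lev)
    out <- unclass(table(true, pred))
  } else {
    if (any(true < 0 | true >= n_class | pred < 0 | pred >= n_class)) {
      stop("labels out of range", call. = FALSE)
    }
    true <- factor(true, levels = 0:(n_class - 1L))
    pred <- factor(pred, levels = 0:(n_class - 1L))
    out <- unclass(table(true, pred))
  }
  names(dimnames(out)) <- c("true", "pred")
  out
}
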