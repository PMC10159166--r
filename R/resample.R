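#' Balanced random under-sampling of majority classes
#'
#' Draws, without replacement and uniformly within each class, `n_min`
#' indices per class where `n_min` is the size of the least represented
#' class (which is therefore taken in full). Uses the current RNG stream;
#' seed upstream for reproducibility.
#'
#' @param labels factor (or coercible) of class labels; all classes must be
#'   present with at least 4 members.
#' @return integer vector of `n_classes * n_min` row indices.
#' @export
balanced_undersample <- function(labels) {
  y <- factor(labels)
  counts <- table(y)
  if (nlevels(y) < 2L || any(counts == 0L)) {
    stop("a class is absent from `labels`", call. = FALSE)
  }
  if (min(counts) < 4L) stop("minimum class count must be >= 4", call. = FALSE)
  n_min <- min(counts)
  unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    if (length(idx) == n_min) idx else sample(idx, n_min)
  }), use.names = FALSE)
}

#' Stratified 50:50 train/test split of a balanced index set
#'
#' Per class, `floor(n/2)` indices go to the training half and the
#' remainder to the test half; the two halves are disjoint and their union
#' is the input.
#'
#' @param indices integer row indices (e.g. from [balanced_undersample()]).
#' @param labels labels for the full table; `labels[indices]` is split.
#' @return list with integer vectors `train` and `test`.
#' @export
split_half <- function(indices, labels) {
  y <- factor(labels)[indices]
  if (any(table(y) < 2L)) {
    stop("every class needs at least 2 members to split", call. = FALSE)
  }
  train <- integer(0)
  test <- integer(0)
  for (lv in levels(y)) {
    idx <- sample(indices[y == lv])
    n_tr <- floor(length(idx) / 2)
    train <- c(train, idx[seq_len(n_tr)])
    test <- c(test, idx[(n_tr + 1L):length(idx)])
  }
  list(train = train, test = test)
}

#' Monte Carlo under-sampling benchmark
#'
#' For each of `R` draws: under-sample to a balanced subset, split 50:50
#' with stratification, optionally refit a PCA on the training half and
#' project both halves, then fit every classifier and record its 3x3
#' test-set confusion matrix. All classifiers see identical draws (common
#' random numbers), so paired per-draw comparisons are valid, and the whole
#' procedure is reproducible from the master seed.
#'
#' @param table a normalized feature table (or an already reduced table).
#' @param specs list of [make_classifier()] specs, or character names.
#' @param R number of Monte Carlo draws.
#' @param seed master integer seed.
#' @param space `"15d"` to use the feature columns as-is, `"7d"` to reduce
#'   per draw by PCA fitted on the training half.
#' @param pca_threshold cumulative explained-variance threshold used to
#'   pick the number of components when `pca_k` is `NULL`.
#' @param pca_k fixed number of components (overrides the threshold).
#' @param pca_global optionally a [fit_pca()] model fitted once on the
#'   whole table, reproducing a global-fit variant; default `NULL` refits
#'   per draw on the training half only (leakage-free).
#' @return named list (one element per classifier) of `confusion_ensemble`
#'   objects: lists of R confusion matrices with the draw metadata attached.
#' @export
run_benchmark <- function(table, specs = classifier_names(), R = 1000L,
                          seed = 1L, space = c("15d", "7d"),
                          pca_threshold = 0.90, pca_k = NULL,
                          pca_global = NULL) {
  space <- match.arg(space)
  if (R < 1L) stop("`R` must be >= 1", call. = FALSE)
  if (is.character(specs)) specs <- lapply(specs, make_classifier)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  labels <- table$stimulus
  label_cols <- c("block_id", "stimulus", "species")
  is_reduced <- isTRUE(attr(table, "reduced"))
  feat_cols <- if (is_reduced) {
    setdiff(names(table), label_cols)
  } else feature_columns(table)
  X_all <- as.matrix(table[, feat_cols])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, R)
  clf_seeds <- matrix(sample.int(.Machine$integer.max - 1L, R * length(specs)),
                      nrow = R)

  ensembles <- lapply(specs, function(s) vector("list", R))
  for (i in seq_len(R)) {
    set.seed(draw_seeds[i])
    idx <- balanced_undersample(labels)
    sp <- split_half(idx, labels)
    Xtr <- X_all[sp$train, , drop = FALSE]
    Xte <- X_all[sp$test, , drop = FALSE]
    ytr <- factor(labels[sp$train])
    yte <- factor(labels[sp$test], levels = levels(ytr))
    if (space == "7d" && !is_reduced) {
      model <- if (is.null(pca_global)) {
        tr_tab <- table[sp$train, , drop = FALSE]
        attr(tr_tab, "normalized") <- attr(table, "normalized")
        fit_pca(tr_tab)
      } else pca_global
      k <- if (is.null(pca_k)) select_components(model, pca_threshold) else pca_k
      rot <- model$rotation[, seq_len(k), drop = FALSE]
      Xtr <- sweep(Xtr, 2L, model$center) %*% rot
      Xte <- sweep(Xte, 2L, model$center) %*% rot
    }
    for (j in seq_along(specs)) {
      s <- specs[[j]]
      s$seed <- clf_seeds[i, j]
      pred <- fit_predict(s, Xtr, ytr, Xte)
      ensembles[[j]][[i]] <- confusion_matrix(yte, pred)
    }
  }
  lapply(ensembles, function(e) {
    structure(e, class = "confusion_ensemble", R = R, seed = seed,
              space = space)
  })
}

#' @export
print.confusion_ensemble <- function(x, ...) {
  cat(sprintf("confusion_ensemble: %d draws (space %s)\n", length(x),
              attr(x, "space") %||% "?"))
  cat("ensemble-average row-normalized matrix:\n")
  print(round(average_confusion(x), 3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble-average row-normalized confusion matrix
#'
#' Each per-draw matrix is row-normalized (rows sum to 1, i.e. per-class
#' rates on the test set) and the element-wise mean over the ensemble is
#' returned.
#'
#' @param ensemble a `confusion_ensemble` (or plain list of count
#'   matrices).
#' @return 3x3 numeric matrix whose rows sum to 1.
#' @export
average_confusion <- function(ensemble) {
  if (length(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  norm <- lapply(ensemble, function(C) {
    rs <- rowSums(C)
    if (any(rs == 0)) stop("confusion matrix has a zero row", call. = FALSE)
    C / rs
  })
  Reduce(`+`, norm) / length(norm)
}
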