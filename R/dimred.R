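#' Principal component analysis of a feature table
#'
#' Eigendecomposition of the sample covariance of the centered (typically
#' min-max normalized, not z-scored) features. The loading signs follow
#' the convention that the largest-magnitude element of each component is
#' positive.
#'
#' @param table a feature table with more rows than features and no
#'   non-finite values.
#' @return object of class `pca_model`: `center`, orthonormal `rotation`,
#'   `sdev` and explained-variance `ratios` (non-increasing, summing to 1).
#' @export
fit_pca <- function(table) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats])
  if (nrow(X) <= ncol(X)) {
    stop("need more rows than features to fit the PCA", call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = pr$center, rotation = rot, sdev = pr$sdev,
                 ratios = pr$sdev^2 / sum(pr$sdev^2),
                 features = feats),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cum <- cumsum(x$ratios)
  cat(sprintf("PCA model on %d features; components for 90%%: %d\n",
              length(x$features), select_components(x, 0.9)))
  print(round(utils::head(cum, 8), 4))
  invisible(x)
}

#' Number of components needed to reach a cumulative variance threshold
#'
#' @param model a [fit_pca()] model.
#' @param threshold fraction of total variance in (0, 1].
#' @return smallest `k` with cumulative explained-variance ratio >=
#'   `threshold`.
#' @export
select_components <- function(model, threshold = 0.90) {
  stopifnot(inherits(model, "pca_model"))
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  cum <- cumsum(model$ratios)
  which(cum >= threshold - 1e-12)[1]
}

#' Project a feature table onto the first k principal components
#'
#' Scores are `(X - center) %*% rotation[, 1:k]`; label columns are
#' carried through unchanged.
#'
#' @param model a [fit_pca()] model.
#' @param table feature table with the same feature columns.
#' @param k number of components, `1 <= k <= n_features`.
#' @return data.frame of labels plus `PC1 ... PCk`.
#' @export
pca_transform <- function(model, table, k) {
  stopifnot(inherits(model, "pca_model"))
  p <- length(model$features)
  if (k < 1L || k > p) stop("`k` out of range", call. = FALSE)
  X <- as.matrix(table[, model$features])
  scores <- sweep(X, 2L, model$center) %*% model$rotation[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  label_cols <- setdiff(names(table), model$features)
  out <- cbind(table[, label_cols, drop = FALSE], as.data.frame(scores))
  attr(out, "reduced") <- TRUE
  out
}
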