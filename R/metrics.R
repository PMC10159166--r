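#' Multiclass classification accuracy (mean per-class recall)
#'
#' Average over classes of the diagonal fraction of each confusion-matrix
#' row, i.e. the mean per-class recall. For a balanced test set this
#' equals the usual trace/total accuracy.
#'
#' @param C square confusion count matrix (true in rows, predicted in
#'   columns) with positive row sums.
#' @return value in `[0, 1]`.
#' @export
accuracy <- function(C) {
  rs <- rowSums(C)
  if (any(rs == 0)) stop("confusion matrix has a zero row", call. = FALSE)
  mean(diag(C) / rs)
}

#' Multiclass balanced accuracy
#'
#' One-vs-rest sensitivity and specificity per class, averaged:
#' `mean_k (Sen_k + Spe_k) / 2`.
#'
#' @inheritParams accuracy
#' @return value in `[0, 1]`.
#' @export
balanced_accuracy <- function(C) {
  oc <- .ovr_counts(C)
  spe_den <- oc$tn + oc$fp
  if (any(oc$tp + oc$fn == 0) || any(spe_den == 0)) {
    stop("degenerate confusion matrix: a one-vs-rest denominator is zero",
         call. = FALSE)
  }
  sen <- oc$tp / (oc$tp + oc$fn)
  spe <- oc$tn / spe_den
  mean((sen + spe) / 2)
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's multiclass generalization:
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `t_k` the per-class truth totals, `p_k` the prediction totals,
#' `c` the correctly classified count and `s` the total. A zero
#' denominator returns 0 by convention.
#'
#' @inheritParams accuracy
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(C) {
  s <- sum(C)
  cc <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- cc * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Macro-averaged F-beta score
#'
#' Per class, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F = (1 + beta^2) * Pre * Rec / (beta^2 * Pre + Rec)`, with `F = 0`
#' when `Pre + Rec = 0` (and a class never predicted contributes
#' precision 0). The unweighted macro mean over classes is returned;
#' `beta = 1` gives the F1 score.
#'
#' @inheritParams accuracy
#' @param beta weight of recall relative to precision.
#' @return value in `[0, 1]`.
#' @export
f_beta <- function(C, beta = 1) {
  oc <- .ovr_counts(C)
  pre <- ifelse(oc$tp + oc$fp == 0, 0, oc$tp / (oc$tp + oc$fp))
  rec <- ifelse(oc$tp + oc$fn == 0, 0, oc$tp / (oc$tp + oc$fn))
  den <- beta^2 * pre + rec
  f <- ifelse(den == 0, 0, (1 + beta^2) * pre * rec / den)
  mean(f)
}

# one-vs-rest counts per class
.ovr_counts <- function(C) {
  C <- as.matrix(C)
  s <- sum(C)
  tp <- diag(C)
  fn <- rowSums(C) - tp
  fp <- colSums(C) - tp
  list(tp = tp, fn = fn, fp = fp, tn = s - tp - fn - fp)
}

#' All four metrics of one confusion matrix
#'
#' @inheritParams accuracy
#' @return named numeric vector `acc`, `bal_acc`, `f1`, `mcc`.
#' @export
metric_set <- function(C) {
  c(acc = accuracy(C), bal_acc = balanced_accuracy(C), f1 = f_beta(C),
    mcc = mcc(C))
}

#' Per-draw metric distributions of a confusion ensemble
#'
#' Computes accuracy, balanced accuracy, macro F1 and MCC for every matrix
#' of the ensemble and attaches normal-fit summaries (sample mean and sd
#' per metric).
#'
#' @param ensemble a `confusion_ensemble` (list of confusion matrices).
#' @return data.frame of class `metric_distribution` with columns `draw`,
#'   `acc`, `bal_acc`, `f1`, `mcc`; the `summary` attribute holds the
#'   normal-fit means and sds.
#' @export
metric_distributions <- function(ensemble) {
  if (length(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  vals <- t(vapply(ensemble, metric_set, numeric(4)))
  out <- data.frame(draw = seq_len(nrow(vals)), vals)
  fit <- rbind(mean = colMeans(vals), sd = apply(vals, 2L, stats::sd))
  attr(out, "summary") <- fit
  class(out) <- c("metric_distribution", "data.frame")
  out
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("metric_distribution over %d draws; normal-fit summary:\n",
              nrow(x)))
  print(round(attr(x, "summary"), 4))
  invisible(x)
}
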