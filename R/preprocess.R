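#' High-pass drift removal
#'
#' Removes slow baseline drift from a raw voltage trace with a zero-phase
#' (forward-backward) Butterworth high-pass filter, leaving the
#' high-frequency stochastic component from which features are extracted.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param cutoff high-pass cutoff in Hz; must satisfy `0 < cutoff < fs/2`.
#' @param order filter order (>= 1). Default 2nd order.
#' @return filtered vector, same length as `x`.
#' @examples
#' x <- reference_signal("white", 1024, seed = 1) + 10
#' y <- highpass_filter(x, fs = 10)
#' abs(mean(y)) < 0.05
#' @export
highpass_filter <- function(x, fs, cutoff = 0.05, order = 2L) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("`cutoff` must satisfy 0 < cutoff < fs/2", call. = FALSE)
  }
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  if (length(x) < 3L * order + 1L) {
    stop("input too short for the requested filter order", call. = FALSE)
  }
  bf <- signal::butter(order, W = cutoff / (fs / 2), type = "high")
  # forward-backward filtering with odd-reflection end padding sized to the
  # filter's transient (~ fs/cutoff samples), so offsets and slow trends do
  # not leak in as edge artifacts
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, ceiling(3 * fs / cutoff))
  ext <- c(2 * xc[1] - xc[(pad + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(pad + 1L):(pad + n)]
}

#' Apply the high-pass filter to every block of a block set
#'
#' @param blocks a `block_set`.
#' @inheritParams highpass_filter
#' @return a `block_set` with filtered signals.
#' @export
filter_blocks <- function(blocks, cutoff = 0.05, order = 2L) {
  stopifnot(inherits(blocks, "block_set"))
  blocks$signals <- t(apply(blocks$signals, 1L, highpass_filter,
                            fs = blocks$fs, cutoff = cutoff, order = order))
  blocks
}

#' Segment a signal into non-overlapping fixed-length blocks
#'
#' Splits a long recording into consecutive windows of `block_len` samples;
#' a trailing remainder shorter than `block_len` is discarded.
#'
#' @param x numeric vector.
#' @param block_len window length in samples.
#' @return list of numeric vectors (possibly empty).
#' @export
segment_signal <- function(x, block_len) {
  if (block_len < 1L) stop("`block_len` must be >= 1", call. = FALSE)
  n_blocks <- floor(length(x) / block_len)
  if (n_blocks == 0L) return(list())
  lapply(seq_len(n_blocks), function(i) {
    x[((i - 1L) * block_len + 1L):(i * block_len)]
  })
}

#' IQR-based outlier removal on a feature table
#'
#' For each feature, the first and third quartiles (Q1, Q3; linear
#' interpolation between order statistics) and IQR = Q3 - Q1 are computed
#' over all rows. Under the default `rule = "as_printed"` a value is kept
#' when `Q1 - n*IQR < x < Q1 + n*IQR` (note: Q1 on both bounds); under
#' `rule = "conventional"` the upper bound is the usual `Q3 + n*IQR`. A row
#' is dropped when any feature violates its band, or when any feature value
#' is non-finite (which is how degenerate blocks flagged by the extractors
#' are absorbed). A feature with zero IQR contributes an equality band
#' (only values equal to its Q1 pass) and raises a warning.
#'
#' @param table a feature table (see [extract_feature_table()]), not yet
#'   normalized.
#' @param n positive IQR multiplier (default 6).
#' @param rule `"as_printed"` or `"conventional"`.
#' @return list with `table` (kept rows) and `kept` (logical mask, length
#'   `nrow(table)`).
#' @export
remove_outliers <- function(table, n = 6,
                            rule = c("as_printed", "conventional")) {
  rule <- match.arg(rule)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (nrow(table) == 0L) stop("feature table is empty", call. = FALSE)
  if (isTRUE(attr(table, "normalized"))) {
    stop("outlier removal expects an unnormalized feature table",
         call. = FALSE)
  }
  feats <- feature_columns(table)
  kept <- rep(TRUE, nrow(table))
  for (f in feats) {
    x <- table[[f]]
    ok <- is.finite(x)
    kept <- kept & ok
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr == 0) {
      warning(sprintf("feature '%s' has zero IQR; equality-band filtering", f),
              call. = FALSE)
      inside <- ok & (x == q[1])
    } else {
      hi <- if (rule == "as_printed") q[1] + n * iqr else q[2] + n * iqr
      inside <- ok & (x > q[1] - n * iqr) & (x < hi)
    }
    kept <- kept & inside
  }
  out <- table[kept, , drop = FALSE]
  attr(out, "normalized") <- attr(table, "normalized")
  list(table = out, kept = kept)
}

#' Fraction of rows retained as the IQR multiplier varies
#'
#' Applies [remove_outliers()] for each value of `n` and reports the
#' fraction of rows kept, reproducing the retention-vs-n curve used to
#' choose the outlier threshold.
#'
#' @inheritParams remove_outliers
#' @param n_values numeric vector of IQR multipliers.
#' @return numeric vector of retained fractions, named by `n`.
#' @export
retention_curve <- function(table, n_values = 1:10,
                            rule = c("as_printed", "conventional")) {
  rule <- match.arg(rule)
  if (length(n_values) == 0L) return(numeric(0))
  out <- vapply(n_values, function(n) {
    mean(suppressWarnings(remove_outliers(table, n = n, rule = rule))$kept)
  }, numeric(1))
  names(out) <- n_values
  out
}

#' Min-max normalization of a feature table to [0, 1]
#'
#' Rescales every feature column to `(x - min) / (max - min)`. Row order
#' and label columns are preserved. A constant feature cannot be scaled and
#' raises an error naming it.
#'
#' @param table a feature table.
#' @return the table with features in `[0, 1]` and the `normalized`
#'   attribute set.
#' @export
minmax_normalize <- function(table) {
  feats <- feature_columns(table)
  for (f in feats) {
    x <- table[[f]]
    if (any(!is.finite(x))) {
      stop(sprintf("feature '%s' contains non-finite values; run remove_outliers() first", f),
           call. = FALSE)
    }
    rng <- range(x)
    if (rng[1] == rng[2]) {
      stop(sprintf("feature '%s' is constant and cannot be min-max scaled", f),
           call. = FALSE)
    }
    table[[f]] <- (x - rng[1]) / (rng[2] - rng[1])
  }
  attr(table, "normalized") <- TRUE
  table
}
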