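#' Names of the fifteen block features
#'
#' Canonical column order used throughout the package: descriptive moments
#' (`mean`, `variance`, `skewness`, `kurtosis`, `iqr`), Hjorth parameters,
#' fractal/long-memory exponents (`dfa_alpha`, `hurst`), `wp_entropy`
#' (wavelet-packet Shannon entropy), `spectral_power`, higher-order
#' standardized moments (`superskewness`, `superflatness`), `fano`
#' (variance-to-mean ratio) and `corr_dim` (correlation dimension).
#'
#' @return character vector of length 15.
#' @export
feature_names <- function() {
  c("mean", "variance", "skewness", "kurtosis", "iqr",
    "hjorth_mobility", "hjorth_complexity", "dfa_alpha", "hurst",
    "wp_entropy", "spectral_power", "superskewness", "superflatness",
    "fano", "corr_dim")
}

# feature columns present in a feature table
feature_columns <- function(table) {
  intersect(feature_names(), names(table))
}

#' Feature-extraction configuration
#'
#' Tunable parameters of the nonlinear feature estimators. Defaults follow
#' common practice for 1024-sample windows: DFA with linear detrending over
#' >= 10 log-spaced box sizes in `[4, N/4]`; classical rescaled-range Hurst
#' over log-spaced window sizes in `[16, N/4]`; full wavelet-packet
#' decomposition with the `db4` filter to level 3 (8 leaf bands);
#' correlation dimension by Grassberger-Procaccia with embedding dimension
#' `m = 5`, delay `tau = 1`, a log radius grid spanning 1--50% of the
#' attractor diameter with the slope read off the middle third, and at most
#' `cd_max_points` evenly subsampled embedded points for the pair sums.
#'
#' @param dfa_min_box,dfa_max_frac,dfa_n_boxes DFA box-size grid: smallest
#'   box, largest box as a fraction of N, number of log-spaced sizes.
#' @param rs_min_win,rs_max_frac,rs_n_wins R/S window-size grid.
#' @param wavelet wavelet filter name (currently `"db4"`).
#' @param wp_level wavelet-packet decomposition level.
#' @param cd_m,cd_tau,cd_max_points,cd_r_range,cd_n_r correlation-dimension
#'   embedding dimension, delay, point budget, radius range (fractions of
#'   the diameter) and radius-grid size.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(dfa_min_box = 4L, dfa_max_frac = 0.25,
                           dfa_n_boxes = 12L,
                           rs_min_win = 16L, rs_max_frac = 0.25,
                           rs_n_wins = 10L,
                           wavelet = "db4", wp_level = 3L,
                           cd_m = 5L, cd_tau = 1L, cd_max_points = 400L,
                           cd_r_range = c(0.01, 0.5), cd_n_r = 21L) {
  stopifnot(dfa_min_box >= 4L, dfa_max_frac < 0.5, wp_level >= 1L,
            cd_m >= 2L, cd_tau >= 1L)
  structure(list(dfa_min_box = dfa_min_box, dfa_max_frac = dfa_max_frac,
                 dfa_n_boxes = dfa_n_boxes, rs_min_win = rs_min_win,
                 rs_max_frac = rs_max_frac, rs_n_wins = rs_n_wins,
                 wavelet = wavelet, wp_level = as.integer(wp_level),
                 cd_m = as.integer(cd_m), cd_tau = as.integer(cd_tau),
                 cd_max_points = as.integer(cd_max_points),
                 cd_r_range = cd_r_range, cd_n_r = as.integer(cd_n_r)),
            class = "feature_config")
}

#' Descriptive and higher-order moments of a block
#'
#' Population variance (divide by N) and sigma-standardized central moments
#' `E[(x - mu)^k] / sigma^k` for k = 3..6: skewness, kurtosis (Gaussian
#' reference 3, not excess), superskewness and superflatness (Gaussian
#' reference 15). The IQR uses linear-interpolation quartiles and the Fano
#' factor is the raw variance-to-mean ratio. Degenerate inputs (constant
#' block; near-zero mean for the Fano factor) yield `NaN` flags that the
#' outlier-removal stage later absorbs.
#'
#' @param x numeric vector, length >= 4.
#' @return named numeric vector: `mean`, `variance`, `skewness`,
#'   `kurtosis`, `superskewness`, `superflatness`, `iqr`, `fano`.
#' @examples
#' moments(c(1, 2, 3, 4))
#' @export
moments <- function(x) {
  if (length(x) < 4L) stop("need at least 4 samples", call. = FALSE)
  mu <- mean(x)
  d <- x - mu
  sig2 <- mean(d^2)
  s <- sqrt(sig2)
  std_mom <- function(k) if (s > 0) mean(d^k) / s^k else NaN
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  fano <- if (abs(mu) < 1e-12) NaN else sig2 / mu
  c(mean = mu, variance = sig2,
    skewness = std_mom(3), kurtosis = std_mom(4),
    superskewness = std_mom(5), superflatness = std_mom(6),
    iqr = q[2] - q[1], fano = fano)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of
#' the first difference divided by the mobility of the signal. For unit
#' white noise the expected values are `sqrt(2)` and `sqrt(3)/sqrt(2)`.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return named numeric vector `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  pvar <- function(v) mean((v - mean(v))^2)
  v0 <- pvar(x)
  d1 <- diff(x)
  v1 <- pvar(d1)
  if (v0 == 0 || v1 == 0) {
    stop("degenerate input: zero variance in signal or first difference",
         call. = FALSE)
  }
  v2 <- pvar(diff(d1))
  mob <- sqrt(v1 / v0)
  c(mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Integrates the mean-removed series, computes the RMS of linearly
#' detrended fluctuations in non-overlapping boxes for a log-spaced grid of
#' box sizes, and returns the least-squares slope of `log F(n)` versus
#' `log n`. Theoretical values: 0.5 for white noise, 1.5 for a random walk,
#' `H` for fractional Gaussian noise.
#'
#' @param x numeric vector, length >= 256.
#' @param cfg a [feature_config()].
#' @return scaling exponent `alpha`.
#' @export
dfa_alpha <- function(x, cfg = feature_config()) {
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples", call. = FALSE)
  sizes <- .log_sizes(cfg$dfa_min_box, floor(n * cfg$dfa_max_frac),
                      cfg$dfa_n_boxes)
  if (length(sizes) < 4L) {
    stop("fewer than 4 usable DFA box sizes", call. = FALSE)
  }
  y <- cumsum(x - mean(x))
  fl <- vapply(sizes, function(b) .dfa_fluct(y, b), numeric(1))
  ok <- fl > 0
  if (sum(ok) < 4L) return(NaN)
  unname(stats::coef(stats::lm(log(fl[ok]) ~ log(sizes[ok])))[2])
}

# RMS of linearly detrended fluctuations at one box size (vectorized over
# boxes via closed-form least squares on the common time grid).
.dfa_fluct <- function(y, b) {
  nb <- floor(length(y) / b)
  Y <- matrix(y[seq_len(nb * b)], nrow = b)
  t <- seq_len(b)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  ybar <- colMeans(Y)
  slope <- as.numeric(crossprod(tc, Y)) / stt
  # residual sum of squares per box: SS_y - slope^2 * stt
  ssy <- colSums(Y^2) - b * ybar^2
  rss <- pmax(ssy - slope^2 * stt, 0)
  sqrt(mean(rss) / b)
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Classical R/S estimator: for each log-spaced window size the series is
#' split into non-overlapping windows, the rescaled range R/S is averaged
#' over windows, and `H` is the slope of `log(R/S)` versus `log(window)`.
#' Windows with zero standard deviation are skipped.
#'
#' @inheritParams dfa_alpha
#' @return Hurst exponent estimate.
#' @export
hurst_rs <- function(x, cfg = feature_config()) {
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples", call. = FALSE)
  sizes <- .log_sizes(cfg$rs_min_win, floor(n * cfg$rs_max_frac),
                      cfg$rs_n_wins)
  rs <- vapply(sizes, function(w) {
    nw <- floor(n / w)
    X <- matrix(x[seq_len(nw * w)], nrow = w)
    vals <- apply(X, 2L, function(seg) {
      z <- seg - mean(seg)
      s <- sqrt(mean(z^2))
      if (s == 0) return(NA_real_)
      ycum <- cumsum(z)
      (max(ycum) - min(ycum)) / s
    })
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L) stop("all R/S windows degenerate", call. = FALSE)
  unname(stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

.log_sizes <- function(lo, hi, k) {
  if (hi <= lo) return(integer(0))
  sort(unique(round(exp(seq(log(lo), log(hi), length.out = k)))))
}

#' Wavelet-packet Shannon entropy
#'
#' Performs a full wavelet-packet decomposition (default: `db4`, level 3,
#' giving 8 leaf bands; periodized orthogonal filter bank), normalizes the
#' leaf-node energies to probabilities and returns their Shannon entropy in
#' nats. The entropy is bounded by `log(2^level)`: maximal for spectrally
#' flat (white) signals, small when the energy concentrates in one band
#' (narrowband tones).
#'
#' @inheritParams dfa_alpha
#' @return entropy in nats.
#' @export
wavelet_packet_entropy <- function(x, cfg = feature_config()) {
  filt <- .wavelet_filter(cfg$wavelet)
  if (length(x) < 2^cfg$wp_level * length(filt$g)) {
    stop("block too short for the requested decomposition level",
         call. = FALSE)
  }
  e <- .wp_energies(x, filt, cfg$wp_level)
  tot <- sum(e)
  if (tot == 0) stop("zero total energy", call. = FALSE)
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Average spectral power
#'
#' Mean squared value of the block, `(1/N) * sum(x^2)`, equal by Parseval's
#' theorem to the mean periodogram energy.
#'
#' @param x numeric vector.
#' @return non-negative scalar.
#' @export
spectral_power <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  mean(x^2)
}

#' Grassberger-Procaccia correlation dimension
#'
#' Delay-embeds the block (default `m = 5`, `tau = 1`), computes the
#' correlation sum C(r) over a log-spaced radius grid spanning 1--50% of
#' the attractor diameter, and returns the slope of `log C` versus `log r`
#' over the middle third of the grid. For a pair-sum budget, at most
#' `cd_max_points` evenly spaced embedded points are used. A noise-free
#' sinusoid (a limit cycle) has dimension ~1; iid noise fills the embedding
#' space. A constant block returns 0.
#'
#' @inheritParams dfa_alpha
#' @return correlation-dimension estimate (>= 0).
#' @export
correlation_dimension <- function(x, cfg = feature_config()) {
  n <- length(x)
  if (n < 512L) stop("need at least 512 samples", call. = FALSE)
  m <- cfg$cd_m
  tau <- cfg$cd_tau
  np <- n - (m - 1L) * tau
  emb <- sapply(seq_len(m), function(j) x[(1L + (j - 1L) * tau):((j - 1L) * tau + np)])
  if (np > cfg$cd_max_points) {
    keep <- round(seq(1L, np, length.out = cfg$cd_max_points))
    emb <- emb[keep, , drop = FALSE]
  }
  d <- as.numeric(stats::dist(emb))
  dmax <- max(d)
  if (dmax == 0) return(0)
  r <- exp(seq(log(cfg$cd_r_range[1] * dmax), log(cfg$cd_r_range[2] * dmax),
               length.out = cfg$cd_n_r))
  cr <- vapply(r, function(ri) mean(d < ri), numeric(1))
  third <- length(r) / 3
  mid <- seq(ceiling(third) + 1L, floor(2 * third) + 1L)
  ok <- mid[cr[mid] > 0]
  if (length(ok) < 3L) return(NaN)
  max(unname(stats::coef(stats::lm(log(cr[ok]) ~ log(r[ok])))[2]), 0)
}

#' Extract the fifteen features from one block
#'
#' Assembles [moments()], [hjorth()], [dfa_alpha()], [hurst_rs()],
#' [wavelet_packet_entropy()], [spectral_power()] and
#' [correlation_dimension()] into one named feature vector in the
#' [feature_names()] order. Component failures on degenerate input
#' (e.g. a constant block) are propagated as `NaN` flags rather than
#' errors so that the outlier-removal stage can drop the row.
#'
#' @param x numeric vector (one block of samples).
#' @param cfg a [feature_config()].
#' @return named numeric vector of length 15.
#' @export
extract_features <- function(x, cfg = feature_config()) {
  mom <- moments(x)
  safe <- function(expr) tryCatch(expr, error = function(e) NaN)
  hj <- safe(hjorth(x))
  if (length(hj) == 1L) hj <- c(mobility = NaN, complexity = NaN)
  out <- c(mean = unname(mom["mean"]),
           variance = unname(mom["variance"]),
           skewness = unname(mom["skewness"]),
           kurtosis = unname(mom["kurtosis"]),
           iqr = unname(mom["iqr"]),
           hjorth_mobility = unname(hj["mobility"]),
           hjorth_complexity = unname(hj["complexity"]),
           dfa_alpha = safe(dfa_alpha(x, cfg)),
           hurst = safe(hurst_rs(x, cfg)),
           wp_entropy = safe(wavelet_packet_entropy(x, cfg)),
           spectral_power = spectral_power(x),
           superskewness = unname(mom["superskewness"]),
           superflatness = unname(mom["superflatness"]),
           fano = unname(mom["fano"]),
           corr_dim = safe(correlation_dimension(x, cfg)))
  out[feature_names()]
}

#' Build the feature table for a block set
#'
#' Applies [extract_features()] to every block and returns the labeled
#' feature table that flows through outlier removal, normalization, PCA
#' and classification.
#'
#' @param blocks a `block_set` (typically already drift-filtered, see
#'   [filter_blocks()]).
#' @param cfg a [feature_config()].
#' @return data.frame with `block_id`, `stimulus`, `species` and the 15
#'   feature columns; `normalized` attribute `FALSE`.
#' @export
extract_feature_table <- function(blocks, cfg = feature_config()) {
  stopifnot(inherits(blocks, "block_set"))
  feats <- t(apply(blocks$signals, 1L, extract_features, cfg = cfg))
  out <- cbind(blocks$meta, as.data.frame(feats))
  attr(out, "normalized") <- FALSE
  out
}

#' Pearson correlation matrix of the fifteen features
#'
#' @param table a feature table with no non-finite feature values and at
#'   least 3 rows.
#' @return symmetric correlation matrix with unit diagonal. Entries
#'   involving a constant feature are `NA`, with a warning.
#' @export
feature_correlation <- function(table) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats])
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (any(!is.finite(X))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("constant feature(s): %s; correlations undefined",
                    paste(feats[const], collapse = ", ")), call. = FALSE)
  }
  suppressWarnings(stats::cor(X))
}
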