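test_that("moments match direct arithmetic and Gaussian identities", {
  m <- moments(c(1, 2, 3, 4))
  expect_equal(m[["mean"]], 2.5)
  expect_equal(m[["variance"]], 1.25)          # population variance
  expect_equal(m[["skewness"]], 0)
  expect_equal(m[["iqr"]], 1.5)                # interpolated quartiles 1.75/3.25
  expect_equal(m[["fano"]], 1.25 / 2.5)
  set.seed(10)
  g <- moments(rnorm(1e5))
  expect_equal(g[["kurtosis"]], 3, tolerance = 0.1 / 3)
  expect_equal(g[["superflatness"]], 15, tolerance = 1.5 / 15)
  expect_lt(abs(g[["skewness"]]), 0.05)
  expect_lt(abs(g[["superskewness"]]), 0.6)
})

test_that("degenerate inputs are flagged, not silently numeric", {
  m <- moments(rep(2, 100))
  expect_equal(m[["variance"]], 0)
  expect_true(all(is.nan(m[c("skewness", "kurtosis", "superskewness",
                             "superflatness")])))
  # near-zero mean flags the Fano factor
  expect_true(is.nan(moments(c(-1, 1, -1, 1))[["fano"]]))
  expect_error(moments(1:3), "4 samples")
})

test_that("Hjorth parameters match white-noise and sinusoid oracles", {
  # iid: var(diff) = 2 sigma^2, var(diff2) = 6 sigma^2
  set.seed(11)
  vals <- t(replicate(10, hjorth(rnorm(4096))))
  expect_equal(mean(vals[, "mobility"]), sqrt(2), tolerance = 0.05 / sqrt(2))
  expect_equal(mean(vals[, "complexity"]), sqrt(3) / sqrt(2),
               tolerance = 0.05)
  # discrete-difference identity for a sinusoid: mobility = 2 sin(pi f / fs)
  s <- reference_signal("sine", 4000, A = 1, f = 0.1, fs = 10)
  expect_equal(hjorth(s)[["mobility"]], 2 * sin(pi * 0.1 / 10),
               tolerance = 1e-3)
  expect_error(hjorth(rep(1, 100)), "degenerate")
})

test_that("DFA recovers the scaling exponents of reference processes", {
  set.seed(12)
  alpha_white <- mean(replicate(200, dfa_alpha(rnorm(1024))))
  expect_gt(alpha_white, 0.45)
  expect_lt(alpha_white, 0.58)
  alpha_rw <- mean(vapply(1:20, function(s) {
    dfa_alpha(reference_signal("random_walk", 1024, seed = 100 + s))
  }, numeric(1)))
  expect_equal(alpha_rw, 1.5, tolerance = 0.15 / 1.5)
  alpha_fgn <- dfa_alpha(reference_signal("fgn", 4096, H = 0.8, seed = 5))
  expect_equal(alpha_fgn, 0.8, tolerance = 0.1 / 0.8)
  expect_error(dfa_alpha(rnorm(100)), "256")
})

test_that("R/S Hurst estimates track the generating exponent", {
  set.seed(13)
  h_white <- mean(replicate(200, hurst_rs(rnorm(1024))))
  expect_gt(h_white, 0.45)   # known small-sample upward bias
  expect_lt(h_white, 0.62)
  h8 <- hurst_rs(reference_signal("fgn", 4096, H = 0.8, seed = 6))
  expect_equal(h8, 0.8, tolerance = 0.15 / 0.8)
  # monotone in H on matched seeds
  for (s in 1:3) {
    est <- vapply(c(0.2, 0.5, 0.8), function(H) {
      hurst_rs(reference_signal("fgn", 4096, H = H, seed = 30 + s))
    }, numeric(1))
    expect_true(all(diff(est) > 0))
  }
})

test_that("R/S estimates track an independent library implementation", {
  for (s in 1:3) {
    x <- reference_signal("fgn", 4096, H = 0.7, seed = 50 + s)
    expect_equal(hurst_rs(x),
                 pracma::hurstexp(x, display = FALSE)$Hrs,
                 tolerance = 0.1 / 0.7)
  }
})

test_that("DFA is monotone in the generating H on matched seeds", {
  for (s in 1:3) {
    est <- vapply(c(0.2, 0.5, 0.8), function(H) {
      dfa_alpha(reference_signal("fgn", 4096, H = H, seed = 40 + s))
    }, numeric(1))
    expect_true(all(diff(est) > 0))
  }
})

test_that("wavelet-packet entropy separates flat from narrowband spectra", {
  w <- reference_signal("white", 1024, seed = 8)
  expect_gt(wavelet_packet_entropy(w), 0.9 * log(8))
  tone <- reference_signal("sine", 1024, A = 1, f = 0.2, fs = 10)
  expect_lt(wavelet_packet_entropy(tone), 0.5 * log(8))
  expect_error(wavelet_packet_entropy(rep(0, 1024)), "zero total energy")
  # entropy bound holds for arbitrary signals
  set.seed(14)
  for (i in 1:20) {
    x <- cumsum(rnorm(512)) + rnorm(512)
    expect_lte(wavelet_packet_entropy(x), log(8) + 1e-12)
  }
})

test_that("the periodized filter bank conserves energy exactly", {
  set.seed(15)
  x <- rnorm(256)
  filt <- plantstim:::.wavelet_filter("db4")
  st <- plantstim:::.wp_step(x, filt)
  expect_equal(sum(st$a^2) + sum(st$d^2), sum(x^2), tolerance = 1e-10)
  e <- plantstim:::.wp_energies(x, filt, 3L)
  expect_length(e, 8)
  expect_equal(sum(e), sum(x^2), tolerance = 1e-10)
})

test_that("spectral power matches Parseval oracles and scales quadratically", {
  expect_equal(spectral_power(rep(0, 64)), 0)
  s <- reference_signal("sine", 1000, A = 2, f = 0.1, fs = 10) # integer periods
  expect_equal(spectral_power(s), 2, tolerance = 1e-6)
  w <- reference_signal("white", 4096, seed = 9)
  expect_equal(spectral_power(w), 1, tolerance = 0.1)
  expect_equal(spectral_power(3.7 * w), 3.7^2 * spectral_power(w),
               tolerance = 1e-9)
})

test_that("correlation dimension distinguishes limit cycles from noise", {
  s <- reference_signal("sine", 1024, f = 0.37, fs = 10)
  expect_equal(correlation_dimension(s), 1, tolerance = 0.3)
  set.seed(16)
  expect_gt(correlation_dimension(runif(1024)), 2)
  expect_equal(correlation_dimension(rep(3, 1024)), 0)
  expect_error(correlation_dimension(rnorm(200)), "512")
})

test_that("correlation sum agrees with a brute-force oracle", {
  set.seed(17)
  x <- as.numeric(arima.sim(list(ar = 0.6), 600))
  cfg <- feature_config(cd_max_points = 150)
  # independent re-implementation with explicit loops
  m <- cfg$cd_m; tau <- cfg$cd_tau
  np <- length(x) - (m - 1) * tau
  emb <- sapply(1:m, function(j) x[(1 + (j - 1) * tau):((j - 1) * tau + np)])
  keep <- round(seq(1, np, length.out = 150))
  emb <- emb[keep, ]
  n <- nrow(emb)
  d <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) d <- c(d, sqrt(sum((emb[i, ] - emb[j, ])^2)))
  }
  dmax <- max(d)
  r <- exp(seq(log(0.01 * dmax), log(0.5 * dmax), length.out = cfg$cd_n_r))
  cr <- sapply(r, function(ri) mean(d < ri))
  mid <- 8:15
  ok <- mid[cr[mid] > 0]
  slope <- unname(coef(lm(log(cr[ok]) ~ log(r[ok])))[2])
  expect_equal(correlation_dimension(x, cfg), max(slope, 0),
               tolerance = 1e-10)
})

test_that("extract_features assembles a deterministic 15-feature vector", {
  w <- reference_signal("white", 1024, seed = 18)
  fv <- extract_features(w)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  expect_equal(fv[["variance"]], 1, tolerance = 0.15)
  expect_lt(abs(fv[["skewness"]]), 0.3)
  expect_equal(fv[["dfa_alpha"]], 0.5, tolerance = 0.2)
  expect_identical(extract_features(w), fv)
  # constant block: flagged row rather than an error
  fc <- extract_features(rep(2, 1024))
  expect_true(sum(is.nan(fc)) >= 5)
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["corr_dim"]], 0)
})

test_that("feature tables are labeled and reproducible", {
  bs <- generate_dataset(synth_config(class_counts = c(4, 4, 4),
                                      block_len = 512, seed = 2))
  tab <- extract_feature_table(bs)
  expect_equal(nrow(tab), 12)
  expect_true(all(feature_names() %in% names(tab)))
  expect_false(attr(tab, "normalized"))
  expect_identical(extract_feature_table(bs), tab)
})

test_that("feature correlations behave on constructed tables", {
  set.seed(19)
  X <- cbind(rnorm(10000), rnorm(10000), rnorm(10000), rnorm(10000))
  tab <- make_feature_table(X)
  R <- feature_correlation(tab)
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(R[upper.tri(R)]) < 0.05))
  expect_equal(R, t(R))
  # duplicated feature: off-diagonal exactly 1
  tab2 <- make_feature_table(cbind(X[, 1], X[, 1], X[, 2]))
  R2 <- feature_correlation(tab2)
  expect_equal(R2[1, 2], 1)
  # skewness-family features co-vary under imposed skew
  z <- matrix(rnorm(500 * 64), nrow = 500)
  z <- z + sweep(z^2, 1, seq(0, 0.5, length.out = 500), "*")
  sk <- t(apply(z, 1, function(r) {
    m <- moments(r)
    c(m[["skewness"]], m[["superskewness"]])
  }))
  expect_gt(cor(sk[, 1], sk[, 2]), 0.5)
})
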