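# Shared fixtures: all built in code at test time.

# three well-separated 2-D Gaussian blobs
make_blobs <- function(n_per, dist = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, dist, 0, 0, dist), ncol = 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(2 * n_per, sd = sd), ncol = 2), 2, centers[k, ], "+")
  }))
  list(X = X, y = factor(rep(c("a", "b", "c"), each = n_per)))
}

# random 3x3 confusion count matrix with positive row sums
random_confusion <- function(max_count = 50) {
  repeat {
    C <- matrix(sample(0:max_count, 9, replace = TRUE), 3, 3)
    if (all(rowSums(C) > 0)) return(C)
  }
}

# rebuild label vectors from a count matrix, then tally one-vs-rest
# counts by brute-force element loops (independent of the package path)
tally_oracle <- function(C) {
  k <- nrow(C)
  true <- integer(0)
  pred <- integer(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      true <- c(true, rep(i, C[i, j]))
      pred <- c(pred, rep(j, C[i, j]))
    }
  }
  per_class <- lapply(seq_len(k), function(cl) {
    tp <- sum(true == cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    fp <- sum(true != cl & pred == cl)
    tn <- sum(true != cl & pred != cl)
    list(tp = tp, fn = fn, fp = fp, tn = tn)
  })
  list(true = true, pred = pred, per_class = per_class)
}

# a small feature table with the canonical label columns and a subset of
# feature columns filled from the supplied matrix
make_feature_table <- function(X, stimulus = NULL,
                               features = feature_names()[seq_len(ncol(X))]) {
  n <- nrow(X)
  if (is.null(stimulus)) {
    stimulus <- factor(rep(c("NaCl", "H2SO4", "O3"), length.out = n))
  }
  tab <- data.frame(block_id = seq_len(n), stimulus = stimulus,
                    species = factor(rep(c("tomato", "cabbage"),
                                         length.out = n)))
  for (j in seq_along(features)) tab[[features[j]]] <- X[, j]
  attr(tab, "normalized") <- FALSE
  tab
}

# closed-form two-sample Hotelling T-squared F statistic
hotelling_two_sample_F <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  d <- colMeans(x1) - colMeans(x2)
  Sp <- ((n1 - 1) * cov(x1) + (n2 - 1) * cov(x2)) / (n1 + n2 - 2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(Sp, d))
  list(T2 = T2,
       F = (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * T2,
       df1 = p, df2 = n1 + n2 - p - 1)
}
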