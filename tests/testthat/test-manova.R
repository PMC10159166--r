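test_that("scatter decomposition satisfies W + B = total", {
  set.seed(40)
  x <- matrix(rnorm(90 * 3), ncol = 3)
  g <- factor(rep(c("a", "b", "c"), each = 30))
  sc <- scatter_matrices(x, g)
  total <- crossprod(scale(x, scale = FALSE))
  expect_equal(sc$W + sc$B, total, tolerance = 1e-8, ignore_attr = TRUE)
  # identical groups: B = 0 exactly
  x2 <- rbind(x[1:30, ], x[1:30, ])
  sc2 <- scatter_matrices(x2, factor(rep(c("a", "b"), each = 30)))
  expect_equal(max(abs(sc2$B)), 0)
  # single-coordinate offset: B has rank 1
  x3 <- x
  x3[g == "b", 2] <- x3[g == "b", 2] + 5
  sc3 <- scatter_matrices(x3, g)
  expect_equal(sum(svd(sc3$B)$d > 1e-8), 2)  # 3 groups, 2 offset directions
  x4 <- x[1:60, ]
  x4[31:60, 2] <- x4[31:60, 2] + 5
  sc4 <- scatter_matrices(x4, factor(rep(c("a", "b"), each = 30)))
  expect_equal(sum(svd(sc4$B)$d > 1e-8), 1)
  expect_error(scatter_matrices(x, factor(rep("a", 90))), "2 groups")
})

test_that("eigenvalues of W^-1 B match a direct generalized solve", {
  set.seed(41)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3)
    W <- crossprod(A) + diag(3)           # SPD
    Bh <- matrix(rnorm(9), 3)
    B <- crossprod(Bh)                    # PSD
    lam <- manova_eigenvalues(W, B)
    oracle <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)
    expect_equal(lam, pmax(oracle, 0), tolerance = 1e-8)
    expect_true(all(lam >= 0))
  }
  # B = 0 -> all zero
  expect_equal(manova_eigenvalues(diag(3), matrix(0, 3, 3)), rep(0, 3))
})

test_that("trace statistics satisfy the single-variate identities", {
  st0 <- trace_statistics(0)
  expect_equal(unname(st0), c(0, 1, 0, 0))
  for (lam in c(0.051001, 9.448972, 39.23723, 38.03857, 0.5, 3)) {
    st <- trace_statistics(lam)
    expect_equal(st[["pillai"]], lam / (1 + lam))
    expect_equal(st[["wilks"]], 1 / (1 + lam))
    expect_equal(st[["hotelling"]], lam)
    expect_equal(st[["roy"]], lam)
    expect_equal(st[["pillai"]], st[["hotelling"]] / (1 + st[["hotelling"]]))
    expect_equal(st[["wilks"]], 1 - st[["pillai"]], tolerance = 1e-12)
  }
  # multi-variate case
  st <- trace_statistics(c(2, 0.5))
  expect_equal(st[["pillai"]], 2 / 3 + 0.5 / 1.5)
  expect_equal(st[["wilks"]], (1 / 3) * (1 / 1.5))
  expect_equal(st[["hotelling"]], 2.5)
  expect_equal(st[["roy"]], 2)
  expect_error(trace_statistics(-0.5), ">= 0")
})

test_that("two-group MANOVA equals the closed-form Hotelling T-squared", {
  set.seed(42)
  for (rep in 1:5) {
    x1 <- matrix(rnorm(25 * 3), ncol = 3)
    x2 <- matrix(rnorm(30 * 3), ncol = 3) + 0.5
    res <- oneway_manova(rbind(x1, x2), rep(c("a", "b"), c(25, 30)))
    hc <- hotelling_two_sample_F(x1, x2)
    expect_equal(res$F, rep(hc$F, 4), tolerance = 1e-8)
    expect_equal(res$df1, rep(hc$df1, 4))
    expect_equal(res$df2[1], hc$df2)
    # all four statistics give one identical exact F for 2 groups
    expect_equal(length(unique(round(res$F, 10))), 1)
    # single discriminant eigenvalue = T2 / (n - 2)
    expect_equal(attr(res, "eigenvalues"), hc$T2 / (25 + 30 - 2),
                 tolerance = 1e-8)
  }
})

test_that("three-group results agree with summary.manova", {
  set.seed(43)
  x <- matrix(rnorm(120 * 3), ncol = 3)
  g <- factor(rep(c("a", "b", "c"), each = 40))
  x[g == "b", 1] <- x[g == "b", 1] + 0.7
  res <- oneway_manova(x, g)
  fit <- manova(x ~ g)
  for (nm in c("Pillai", "Wilks", "Hotelling-Lawley", "Roy")) {
    sm <- summary(fit, test = nm)$stats
    row <- res[res$statistic == c(Pillai = "pillai", Wilks = "wilks",
                                  `Hotelling-Lawley` = "hotelling",
                                  Roy = "roy")[nm], ]
    expect_equal(row$value, unname(sm[1, 2]), tolerance = 1e-6,
                 label = nm)
    expect_equal(row$F, unname(sm[1, 3]), tolerance = 1e-6, label = nm)
    expect_equal(row$df1, unname(sm[1, 4]), label = nm)
    expect_equal(row$df2, unname(sm[1, 5]), label = nm)
  }
})

test_that("strongly separated groups are detected with tiny p-values", {
  set.seed(44)
  x1 <- matrix(rnorm(100 * 3), ncol = 3)
  x2 <- matrix(rnorm(100 * 3), ncol = 3) + 1   # 1 sd offset per coordinate
  res <- oneway_manova(rbind(x1, x2), rep(c("a", "b"), each = 100))
  expect_true(all(res$p_value < 1e-6))
})

test_that("one-sample location test matches the textbook Hotelling form", {
  set.seed(45)
  x <- matrix(rnorm(30 * 3), ncol = 3)
  res <- group_location_test(x)
  m <- colMeans(x)
  T2 <- 30 * drop(t(m) %*% solve(cov(x), m))
  expect_equal(attr(res, "eigenvalues"), T2 / 29, tolerance = 1e-8)
  expect_equal(res$F[1], (30 - 3) / ((30 - 1) * 3) * T2, tolerance = 1e-8)
  expect_equal(res$value[res$statistic == "pillai"],
               (T2 / 29) / (1 + T2 / 29))
  # centered exactly at the reference: all statistics collapse
  xc <- scale(x, scale = FALSE)
  res0 <- group_location_test(xc, reference = 0)
  expect_equal(res0$value[res0$statistic == "pillai"], 0, tolerance = 1e-12)
  expect_equal(res0$value[res0$statistic == "wilks"], 1, tolerance = 1e-12)
  # paired version is the one-sample test on differences
  y <- x + 0.3
  expect_equal(paired_location_test(y, x)$F[1],
               group_location_test(y - x)$F[1])
})

test_that("Wilks and Pillai are invariant under affine metric changes", {
  set.seed(46)
  x <- matrix(rnorm(80 * 3), ncol = 3)
  g <- factor(rep(c("a", "b"), each = 40))
  x[g == "b", ] <- x[g == "b", ] + 0.4
  A <- matrix(c(2, 0.3, 0, 0.1, 1.5, 0, 0, 0.2, 0.7), 3, 3)
  shift <- c(10, -5, 3)
  xt <- sweep(x %*% A, 2, shift, "+")
  r1 <- oneway_manova(x, g)
  r2 <- oneway_manova(xt, g)
  expect_equal(r1$value, r2$value, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("null p-values are approximately uniform", {
  set.seed(47)
  pvals <- replicate(1000, {
    x <- matrix(rnorm(40 * 3), ncol = 3)
    res <- oneway_manova(x, rep(c("a", "b"), each = 20))
    res$p_value[res$statistic == "pillai"]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("singular within-scatter is reported helpfully", {
  x <- matrix(rnorm(40), ncol = 2)
  x <- cbind(x, x[, 1])   # duplicated metric
  expect_error(scatter_within_singular <- oneway_manova(
    x, factor(rep(c("a", "b"), each = 10))), "singular")
})
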