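test_that("under-sampling the study's class counts gives the balanced subset", {
  labels <- factor(rep(c("NaCl", "H2SO4", "O3"), c(628, 1488, 35718)),
                   levels = c("NaCl", "H2SO4", "O3"))
  set.seed(1)
  idx <- balanced_undersample(labels)
  expect_length(idx, 628 * 3)          # 1884 datapoints
  expect_equal(unname(table(labels[idx])), rep(628L, 3), ignore_attr = TRUE)
  expect_false(anyDuplicated(idx) > 0)
  # minority class taken in full
  expect_setequal(idx[labels[idx] == "NaCl"], which(labels == "NaCl"))
  sp <- split_half(idx, labels)
  expect_equal(unname(table(labels[sp$train])), rep(314L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(table(labels[sp$test])), rep(314L, 3),
               ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), idx)
})

test_that("already balanced labels are kept in full", {
  labels <- factor(rep(c("a", "b", "c"), each = 10))
  set.seed(2)
  expect_setequal(balanced_undersample(labels), 1:30)
  sp <- split_half(balanced_undersample(labels), labels)
  expect_equal(unname(table(labels[sp$train])), rep(5L, 3),
               ignore_attr = TRUE)
  # odd counts: floor to train, remainder to test
  lab5 <- factor(rep(c("a", "b", "c"), each = 5))
  sp5 <- split_half(1:15, lab5)
  expect_equal(unname(table(lab5[sp5$train])), rep(2L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(lab5[sp5$test])), rep(3L, 3), ignore_attr = TRUE)
})

test_that("majority-class elements are drawn uniformly", {
  labels <- factor(rep(c("a", "b", "c"), c(5, 7, 9)))
  counts_b <- integer(7)
  counts_c <- integer(9)
  set.seed(3)
  for (i in 1:2000) {
    idx <- balanced_undersample(labels)
    counts_b <- counts_b + tabulate(idx[labels[idx] == "b"] - 5L, 7)
    counts_c <- counts_c + tabulate(idx[labels[idx] == "c"] - 12L, 9)
  }
  expect_true(all(abs(counts_b / 2000 - 5 / 7) < 0.05))
  expect_true(all(abs(counts_c / 2000 - 5 / 9) < 0.05))
})

test_that("every majority-class datapoint is eventually sampled", {
  labels <- factor(rep(c("a", "b", "c"), c(20, 50, 50)))
  seen <- logical(120)
  set.seed(4)
  for (i in 1:200) seen[balanced_undersample(labels)] <- TRUE
  expect_true(all(seen))
})

test_that("errors on absent or tiny classes", {
  expect_error(balanced_undersample(factor(rep("a", 10))), "class")
  labels <- factor(rep(c("a", "b", "c"), c(2, 10, 10)))
  expect_error(balanced_undersample(labels), ">= 4")
  expect_error(split_half(1:3, factor(c("a", "a", "b"))), "at least 2")
})

test_that("the benchmark is reproducible and structurally correct", {
  blobs <- make_blobs(40, sd = 2, seed = 5)
  tab <- make_feature_table(blobs$X, stimulus = blobs$y)
  attr(tab, "normalized") <- TRUE
  e1 <- run_benchmark(tab, specs = c("knn", "gnb"), R = 3, seed = 9)
  e2 <- run_benchmark(tab, specs = c("knn", "gnb"), R = 3, seed = 9)
  expect_identical(e1, e2)
  expect_named(e1, c("knn", "gnb"))
  expect_length(e1$knn, 3)
  # per draw: 20 test rows per class (40 -> 20/20 split), all classifiers
  # see identical draws (common random numbers -> matching row sums)
  for (i in 1:3) {
    expect_equal(sum(e1$knn[[i]]), 60)
    expect_equal(rowSums(e1$knn[[i]]), rowSums(e1$gnb[[i]]))
  }
  e3 <- run_benchmark(tab, specs = "knn", R = 3, seed = 10)
  expect_false(identical(e1$knn, e3$knn))
})

test_that("separable data yields a near-diagonal ensemble", {
  blobs <- make_blobs(60, seed = 6)
  tab <- make_feature_table(blobs$X, stimulus = blobs$y)
  attr(tab, "normalized") <- TRUE
  ens <- run_benchmark(tab, specs = "knn", R = 20, seed = 11)
  avg <- average_confusion(ens$knn)
  expect_gt(mean(diag(avg)), 0.95)
  expect_equal(unname(rowSums(avg)), rep(1, 3), tolerance = 1e-9)
})

test_that("per-draw PCA reduction runs inside the benchmark", {
  set.seed(7)
  X <- matrix(rnorm(180 * 15), ncol = 15)
  X[61:120, 1:5] <- X[61:120, 1:5] + 2
  X[121:180, 6:10] <- X[121:180, 6:10] + 2
  y <- factor(rep(c("a", "b", "c"), each = 60))
  tab <- make_feature_table(X, stimulus = y)
  attr(tab, "normalized") <- TRUE
  ens <- run_benchmark(tab, specs = "knn", R = 3, seed = 12, space = "7d",
                       pca_k = 7)
  expect_length(ens$knn, 3)
  expect_equal(sum(ens$knn[[1]]), 90)
  # fixed-k and threshold selection both work
  ens2 <- run_benchmark(tab, specs = "knn", R = 2, seed = 12, space = "7d",
                        pca_threshold = 0.9)
  expect_equal(sum(ens2$knn[[1]]), 90)
})

test_that("ensemble averaging row-normalizes before the mean", {
  C1 <- diag(c(10, 10, 10))
  C2 <- matrix(c(5, 5, 0, 0, 10, 0, 0, 0, 10), 3, 3, byrow = TRUE)
  avg <- average_confusion(list(C1, C2))
  expect_equal(avg[1, 1], (1 + 0.5) / 2)
  expect_equal(avg[1, 2], 0.25)
  expect_equal(unname(rowSums(avg)), rep(1, 3))
  expect_equal(average_confusion(list(C1, C1)), diag(3) * 1)
  expect_error(average_confusion(list(matrix(0, 3, 3))), "zero row")
  expect_error(average_confusion(list()), "empty")
})
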