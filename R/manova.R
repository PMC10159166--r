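#' Within- and between-group scatter matrices
#'
#' Standard MANOVA decomposition: `W` sums squared deviations from group
#' means, `B` sums `n_g`-weighted squared deviations of group means from
#' the grand mean; `W + B` equals the total scatter.
#'
#' @param x numeric matrix, one row per observation, `p` columns of
#'   dependent variables.
#' @param group factor of group labels (>= 2 levels).
#' @return list with matrices `W`, `B`, the group means and sizes.
#' @export
scatter_matrices <- function(x, group) {
  x <- as.matrix(x)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in `x`", call. = FALSE)
  grand <- colMeans(x)
  p <- ncol(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  means <- list()
  sizes <- integer(0)
  for (lv in levels(group)) {
    xi <- x[group == lv, , drop = FALSE]
    mi <- colMeans(xi)
    ci <- sweep(xi, 2L, mi)
    W <- W + crossprod(ci)
    dm <- mi - grand
    B <- B + nrow(xi) * tcrossprod(dm)
    means[[lv]] <- mi
    sizes[lv] <- nrow(xi)
  }
  list(W = W, B = B, means = means, sizes = sizes)
}

#' Discriminant eigenvalues of W^-1 B
#'
#' @param W within-group scatter matrix (must be invertible).
#' @param B between-group scatter matrix.
#' @param s number of eigenvalues to keep (defaults to all); the number of
#'   discriminant variates is `min(p, groups - 1)`.
#' @return non-negative eigenvalues in decreasing order (negatives below
#'   1e-10 clipped to 0).
#' @export
manova_eigenvalues <- function(W, B, s = NULL) {
  M <- tryCatch(solve(W, B), error = function(e) {
    stop("within-group scatter matrix is singular; remove duplicated or constant metrics",
         call. = FALSE)
  })
  lam <- Re(eigen(M, only.values = TRUE)$values)
  lam <- sort(lam, decreasing = TRUE)
  lam[lam < 0] <- 0
  if (!is.null(s)) lam <- lam[seq_len(s)]
  lam
}

#' MANOVA trace statistics from discriminant eigenvalues
#'
#' Pillai's trace `V = sum(lambda / (1 + lambda))`, Wilks' lambda
#' `prod(1 / (1 + lambda))`, the Hotelling-Lawley trace `sum(lambda)` and
#' Roy's greatest root `max(lambda)`. For a single variate (s = 1) these
#' satisfy `V = U/(1+U)`, `Wilks = 1 - V`, `Roy = U`.
#'
#' @param lambda non-negative eigenvalues of `W^-1 B`.
#' @return named numeric vector `pillai`, `wilks`, `hotelling`, `roy`.
#' @examples
#' trace_statistics(0.051001)
#' @export
trace_statistics <- function(lambda) {
  if (any(lambda < -1e-10)) stop("eigenvalues must be >= 0", call. = FALSE)
  lambda <- pmax(lambda, 0)
  c(pillai = sum(lambda / (1 + lambda)),
    wilks = prod(1 / (1 + lambda)),
    hotelling = sum(lambda),
    roy = max(lambda, 0))
}

#' One-way MANOVA comparing group mean vectors
#'
#' Tests the null hypothesis that the multivariate group means are equal.
#' Reports the four trace statistics with their standard F approximations
#' (Rao's for Wilks, the Pillai and Hotelling-Lawley moment
#' approximations, and the Roy upper-bound F). For two groups all four
#' reduce to the identical exact two-sample Hotelling T-squared F with
#' `df1 = p`, `df2 = n - p - 1`.
#'
#' @inheritParams scatter_matrices
#' @return object of class `manova_result`: a data.frame with columns
#'   `statistic`, `value`, `F`, `R2`, `df1`, `df2`, `p_value`, plus the
#'   eigenvalues in the `eigenvalues` attribute. `R2` is the Pillai-type
#'   effect size `V/s`.
#' @export
oneway_manova <- function(x, group) {
  x <- as.matrix(x)
  group <- factor(group)
  N <- nrow(x)
  p <- ncol(x)
  g <- nlevels(group)
  if (any(table(group) < p + 2L)) {
    stop("each group needs at least p + 2 observations", call. = FALSE)
  }
  sc <- scatter_matrices(x, group)
  s <- min(p, g - 1L)
  lam <- manova_eigenvalues(sc$W, sc$B, s = s)
  st <- trace_statistics(lam)
  q <- g - 1L
  m <- (abs(p - q) - 1) / 2
  n0 <- (N - g - p - 1) / 2

  V <- st[["pillai"]]
  pillai_df1 <- s * (2 * m + s + 1)
  pillai_df2 <- s * (2 * n0 + s + 1)
  pillai_F <- ((2 * n0 + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)

  L <- st[["wilks"]]
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  wilks_df1 <- p * q
  wilks_df2 <- ((N - 1) - (p + q + 1) / 2) * tt - (p * q - 2) / 2
  Lt <- L^(1 / tt)
  wilks_F <- ((1 - Lt) / Lt) * (wilks_df2 / wilks_df1)

  U <- st[["hotelling"]]
  hot_df1 <- s * (2 * m + s + 1)
  hot_df2 <- 2 * (s * n0 + 1)
  hot_F <- hot_df2 * U / (s^2 * (2 * m + s + 1))

  r <- max(p, q)
  roy_df1 <- r
  roy_df2 <- N - g - r + q
  roy_F <- st[["roy"]] * roy_df2 / r

  res <- data.frame(
    statistic = c("pillai", "wilks", "hotelling", "roy"),
    value = unname(st),
    F = c(pillai_F, wilks_F, hot_F, roy_F),
    R2 = V / s,
    df1 = c(pillai_df1, wilks_df1, hot_df1, roy_df1),
    df2 = c(pillai_df2, wilks_df2, hot_df2, roy_df2))
  res$p_value <- stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  structure(res, class = c("manova_result", "data.frame"),
            eigenvalues = lam, n = N, p = p, groups = g)
}

#' One-sample multivariate location test of a group mean
#'
#' Hotelling's one-sample T-squared test of the group mean against a
#' reference vector, expressed through the single discriminant eigenvalue
#' `lambda = T2 / (n - 1)` with `T2 = n * (m - ref)' S^-1 (m - ref)` so
#' that the four trace statistics follow from [trace_statistics()]. The
#' exact F is `lambda * (n - p) / p` on `(p, n - p)` degrees of freedom.
#' This is the "constant/intercept" row of a repeated-measures MANOVA
#' table.
#'
#' @param x numeric matrix of one group's observations (n > p).
#' @param reference mean vector under the null (default all zeros).
#' @return a `manova_result` (see [oneway_manova()]).
#' @export
group_location_test <- function(x, reference = 0) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need n > p observations", call. = FALSE)
  if (length(reference) == 1L) reference <- rep(reference, p)
  m <- colMeans(x) - reference
  S <- stats::cov(x)
  Sm <- tryCatch(solve(S, m), error = function(e) {
    stop("singular covariance matrix", call. = FALSE)
  })
  T2 <- n * sum(m * Sm)
  lam <- T2 / (n - 1)
  st <- trace_statistics(lam)
  Fval <- lam * (n - p) / p
  res <- data.frame(
    statistic = c("pillai", "wilks", "hotelling", "roy"),
    value = unname(st),
    F = Fval,
    R2 = st[["pillai"]],
    df1 = p,
    df2 = n - p)
  res$p_value <- stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  structure(res, class = c("manova_result", "data.frame"),
            eigenvalues = lam, n = n, p = p, groups = 1L)
}

#' Paired location test of per-draw metric differences
#'
#' With common random numbers, draw i of one setting is paired with draw i
#' of the other; the per-draw difference vectors are tested against zero
#' mean with the one-sample location test. This is the paired reading of a
#' repeated-measures comparison of two feature spaces.
#'
#' @param x1,x2 numeric matrices of paired per-draw metrics (same
#'   dimensions, rows aligned by draw).
#' @return a `manova_result`.
#' @export
paired_location_test <- function(x1, x2) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  stopifnot(identical(dim(x1), dim(x2)))
  group_location_test(x1 - x2, reference = 0)
}

#' @export
print.manova_result <- function(x, ...) {
  lam <- attr(x, "eigenvalues")
  cat(sprintf("MANOVA (n = %d, p = %d, groups = %d); eigenvalues: %s\n",
              attr(x, "n"), attr(x, "p"), attr(x, "groups"),
              paste(signif(lam, 6), collapse = ", ")))
  df <- as.data.frame(x)
  df$value <- signif(df$value, 6)
  df$F <- signif(df$F, 6)
  df$R2 <- signif(df$R2, 6)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
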