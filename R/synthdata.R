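#' Configuration for the synthetic plant-signal generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: three
#' chemical-stimulus classes (NaCl, H2SO4, O3) with a strongly unbalanced
#' block count, 1024-sample windows at 10 Hz, and class-conditional
#' stochastic structure. Each class is generated as an AR(1) process plus
#' fractional Gaussian noise with class-specific AR coefficient `phi`,
#' innovation scale `sigma` and Hurst exponent `H`, optionally passed
#' through a mild quadratic skew transform `x + skew * x^2`. Classes
#' therefore differ in variance, spectral slope, long-range dependence and
#' asymmetry -- the feature families the downstream classifiers consume.
#' The per-class values act as means: every block draws its own parameters
#' around them (`jitter_*`), emulating plant-to-plant and
#' experiment-to-experiment heterogeneity. This within-class spread is
#' what produces the substantial overlap of the univariate feature
#' histograms between classes that field recordings show; without it the
#' classes would be trivially separable.
#'
#' The default class counts (60, 144, 3426) preserve the 628 : 1488 : 35718
#' imbalance ratio of the motivating field data at roughly one tenth scale.
#'
#' @param class_counts integer vector of length 3: number of blocks per
#'   stimulus class, ordered (NaCl, H2SO4, O3). All must be >= 4.
#' @param block_len samples per block (>= 64).
#' @param fs sampling rate in Hz.
#' @param phi AR(1) coefficients per class.
#' @param sigma innovation standard deviations per class (arbitrary voltage
#'   units).
#' @param H Hurst exponents of the fGn component per class, each in (0, 1).
#' @param skew quadratic skew-transform strengths per class.
#' @param jitter_phi,jitter_H,jitter_skew standard deviations of the
#'   per-block Gaussian jitter around the class values (phi and H are
#'   clipped to stable/valid ranges).
#' @param jitter_sigma log-scale standard deviation of the per-block
#'   lognormal jitter on the innovation scale.
#' @param species_probs probabilities of (tomato, cabbage); must sum to 1.
#' @param seed master integer seed; per-block substreams are derived from it
#'   so generation is reproducible independently of order.
#' @return An object of class `synth_config`.
#' @seealso [generate_dataset()], [reference_signal()]
#' @export
synth_config <- function(class_counts = c(60L, 144L, 3426L),
                         block_len = 1024L,
                         fs = 10,
                         phi = c(0.2, 0.5, 0.7),
                         sigma = c(1.0, 1.4, 2.0),
                         H = c(0.55, 0.70, 0.85),
                         skew = c(0.00, 0.12, 0.00),
                         jitter_phi = 0.12, jitter_H = 0.10,
                         jitter_sigma = 0.30, jitter_skew = 0.06,
                         species_probs = c(0.5, 0.5),
                         seed = 1L) {
  class_counts <- as.integer(class_counts)
  if (length(class_counts) != 3L || any(is.na(class_counts)) ||
      any(class_counts < 4L)) {
    stop("`class_counts` must be three integers, all >= 4", call. = FALSE)
  }
  if (block_len < 64L) stop("`block_len` must be >= 64", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  for (nm in c("phi", "sigma", "H", "skew")) {
    v <- get(nm)
    if (length(v) != 3L || any(!is.finite(v))) {
      stop(sprintf("`%s` must be a finite numeric vector of length 3", nm),
           call. = FALSE)
    }
  }
  if (any(H <= 0 | H >= 1)) stop("all `H` must lie in (0, 1)", call. = FALSE)
  if (any(sigma <= 0)) stop("all `sigma` must be positive", call. = FALSE)
  if (length(species_probs) != 2L ||
      abs(sum(species_probs) - 1) > 1e-12 || any(species_probs < 0)) {
    stop("`species_probs` must be two non-negative values summing to 1",
         call. = FALSE)
  }
  jit <- c(jitter_phi, jitter_H, jitter_sigma, jitter_skew)
  if (any(!is.finite(jit)) || any(jit < 0)) {
    stop("jitter parameters must be non-negative and finite", call. = FALSE)
  }
  structure(
    list(class_counts = class_counts, block_len = as.integer(block_len),
         fs = fs, phi = phi, sigma = sigma, H = H, skew = skew,
         jitter_phi = jitter_phi, jitter_H = jitter_H,
         jitter_sigma = jitter_sigma, jitter_skew = jitter_skew,
         species_probs = species_probs, seed = as.integer(seed)),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic plant-signal configuration\n")
  cat(sprintf("  blocks: %s (NaCl, H2SO4, O3); block_len %d @ %g Hz\n",
              paste(x$class_counts, collapse = "/"), x$block_len, x$fs))
  cat(sprintf("  phi   %s\n", paste(format(x$phi), collapse = " ")))
  cat(sprintf("  sigma %s\n", paste(format(x$sigma), collapse = " ")))
  cat(sprintf("  H     %s\n", paste(format(x$H), collapse = " ")))
  cat(sprintf("  skew  %s\n", paste(format(x$skew), collapse = " ")))
  cat(sprintf("  seed  %d\n", x$seed))
  invisible(x)
}

stimulus_levels <- function() c("NaCl", "H2SO4", "O3")
species_levels <- function() c("tomato", "cabbage")

#' Generate a labeled synthetic dataset of signal blocks
#'
#' Draws `sum(class_counts)` independent 1024-sample voltage blocks with the
#' class-conditional AR(1) + fGn structure described in [synth_config()].
#' The species label is assigned independently of the stimulus class, so
#' species cannot confound the stimulus classification. One master seed
#' spawns a per-block substream, making the output bit-identical for a
#' given configuration regardless of evaluation order.
#'
#' @param config a [synth_config()] object.
#' @return An object of class `block_set`: a list with `signals` (matrix,
#'   one row per block), `meta` (data.frame with `block_id`, `stimulus`,
#'   `species`), `fs` and the generating `config`.
#' @examples
#' bs <- generate_dataset(synth_config(class_counts = c(5, 6, 7), seed = 1))
#' table(bs$meta$stimulus)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  counts <- config$class_counts
  n_total <- sum(counts)
  cls <- rep(seq_len(3L), counts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  block_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  species <- sample(species_levels(), n_total, replace = TRUE,
                    prob = config$species_probs)

  signals <- matrix(0, nrow = n_total, ncol = config$block_len)
  for (i in seq_len(n_total)) {
    k <- cls[i]
    signals[i, ] <- .synth_block(config$block_len, phi = config$phi[k],
                                 sigma = config$sigma[k], H = config$H[k],
                                 skew = config$skew[k],
                                 jitter = c(config$jitter_phi,
                                            config$jitter_H,
                                            config$jitter_sigma,
                                            config$jitter_skew),
                                 seed = block_seeds[i])
  }
  meta <- data.frame(
    block_id = seq_len(n_total),
    stimulus = factor(stimulus_levels()[cls], levels = stimulus_levels()),
    species = factor(species, levels = species_levels()),
    stringsAsFactors = FALSE)
  structure(list(signals = signals, meta = meta, fs = config$fs,
                 config = config),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("block_set: %d blocks x %d samples @ %g Hz\n",
              nrow(x$signals), ncol(x$signals), x$fs))
  print(table(stimulus = x$meta$stimulus))
  invisible(x)
}

# one block: AR(1) + fGn with per-block parameter jitter, then quadratic
# skew transform
.synth_block <- function(n, phi, sigma, H, skew, jitter = c(0, 0, 0, 0),
                         seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  phi <- min(max(phi + stats::rnorm(1, sd = jitter[1]), -0.95), 0.95)
  H <- min(max(H + stats::rnorm(1, sd = jitter[2]), 0.05), 0.95)
  sigma <- sigma * exp(stats::rnorm(1, sd = jitter[3]))
  skew <- skew + stats::rnorm(1, sd = jitter[4])
  burn <- 100L
  ar <- stats::filter(stats::rnorm(n + burn, sd = sigma), phi,
                      method = "recursive")[(burn + 1L):(burn + n)]
  x <- as.numeric(ar) + .fgn(n, H = H, sd = sigma)
  if (skew != 0) x <- x + skew * x^2
  x
}

# Davies-Harte / circulant-embedding fractional Gaussian noise.
# Uses the current RNG stream.
.fgn <- function(n, H, sd = 1) {
  if (H <= 0 || H >= 1) stop("`H` must lie in (0, 1)", call. = FALSE)
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n, sd = sd))
  m <- 2L * n
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g, rev(g[2:n]))          # length 2n
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0] <- 0            # guard tiny negative eigenvalues
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1] / m) * stats::rnorm(1)
  w[n + 1] <- sqrt(lambda[n + 1] / m) * stats::rnorm(1)
  j <- 2:n
  zr <- stats::rnorm(n - 1)
  zi <- stats::rnorm(n - 1)
  w[j] <- sqrt(lambda[j] / (2 * m)) * complex(real = zr, imaginary = zi)
  w[m - j + 2] <- Conj(w[j])
  sd * Re(stats::fft(w))[1:n]
}

#' Reference signals with analytically known feature values
#'
#' Deterministic or seeded stochastic fixtures used to validate the feature
#' extractors: white Gaussian noise, fractional Gaussian noise (fGn) with a
#' prescribed Hurst exponent, a random walk (integrated white noise), a pure
#' sinusoid and a constant.
#'
#' @param kind one of `"white"`, `"fgn"`, `"random_walk"`, `"sine"`,
#'   `"constant"`.
#' @param n length (>= 64).
#' @param sd standard deviation of the Gaussian innovations (white, fgn,
#'   random_walk).
#' @param H Hurst exponent in (0, 1), fgn only.
#' @param A,f,fs amplitude, frequency (0 < f < fs/2) and sampling rate of
#'   the sinusoid.
#' @param value constant level.
#' @param seed integer seed for the stochastic kinds.
#' @return numeric vector of length `n`.
#' @examples
#' x <- reference_signal("fgn", n = 1024, H = 0.8, seed = 1)
#' @export
reference_signal <- function(kind = c("white", "fgn", "random_walk", "sine",
                                      "constant"),
                             n, sd = 1, H = 0.7, A = 1, f = 1, fs = 10,
                             value = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 64L) stop("`n` must be >= 64", call. = FALSE)
  if (kind %in% c("white", "fgn", "random_walk")) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  switch(kind,
    white = stats::rnorm(n, sd = sd),
    fgn = {
      if (H <= 0 || H >= 1) stop("`H` must lie in (0, 1)", call. = FALSE)
      .fgn(n, H = H, sd = sd)
    },
    random_walk = cumsum(stats::rnorm(n, sd = sd)),
    sine = {
      if (f <= 0 || f >= fs / 2) {
        stop("`f` must satisfy 0 < f < fs/2", call. = FALSE)
      }
      A * sin(2 * pi * f * seq(0, n - 1) / fs)
    },
    constant = rep(value, n))
}

#' Write / read a block set as delimited text
#'
#' The on-disk format is one row per block: `block_id`, `stimulus`,
#' `species`, then `s0 ... s<block_len-1>` sample columns. A JSON sidecar
#' (`<path>.json`) records the generating configuration.
#'
#' @param blocks a `block_set`.
#' @param path CSV path.
#' @return `write_blocks_csv()` returns `path` invisibly;
#'   `read_blocks_csv()` returns a `block_set`.
#' @export
write_blocks_csv <- function(blocks, path) {
  stopifnot(inherits(blocks, "block_set"))
  df <- cbind(blocks$meta, as.data.frame(blocks$signals))
  names(df)[-(1:3)] <- paste0("s", seq_len(ncol(blocks$signals)) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- blocks$config
  cfg_list <- unclass(cfg)
  jsonlite::write_json(c(cfg_list, list(fs = blocks$fs)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blocks_csv
#' @export
read_blocks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_cols <- grep("^s[0-9]+$", names(df))
  meta <- data.frame(
    block_id = df$block_id,
    stimulus = factor(df$stimulus, levels = stimulus_levels()),
    species = factor(df$species, levels = species_levels()))
  structure(list(signals = as.matrix(df[, sample_cols]), meta = meta,
                 fs = NA_real_, config = NULL),
            class = "block_set")
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
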