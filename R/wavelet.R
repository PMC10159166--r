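# Periodized orthogonal wavelet-packet filter bank.
#
# Only the filters needed by the feature suite are bundled; db4 is the
# 8-tap Daubechies filter with 4 vanishing moments. The highpass filter is
# the quadrature mirror of the scaling filter.

.wavelet_filter <- function(name = "db4") {
  g <- switch(name,
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    haar = c(1, 1) / sqrt(2),
    stop(sprintf("unknown wavelet '%s'", name), call. = FALSE))
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1L) * rev(g)
  list(g = g, h = h)
}

# One periodized analysis step: x (even length N) -> approximation and
# detail coefficients of length N/2. Rows of the implied transform are
# even shifts of the filters, so the step is orthonormal and conserves
# energy exactly.
.wp_step <- function(x, filt) {
  N <- length(x)
  L <- length(filt$g)
  half <- N %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% N + 1L
  X <- matrix(x[idx], nrow = half)
  list(a = as.numeric(X %*% filt$g), d = as.numeric(X %*% filt$h))
}

# Leaf-node energies of the full wavelet-packet tree at `level`.
.wp_energies <- function(x, filt, level) {
  nodes <- list(x)
  for (l in seq_len(level)) {
    nodes <- unlist(lapply(nodes, function(nd) {
      st <- .wp_step(nd, filt)
      list(st$a, st$d)
    }), recursive = FALSE)
  }
  vapply(nodes, function(nd) sum(nd^2), numeric(1))
}
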