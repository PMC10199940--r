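# Independent brute-force oracles used to validate the production
# implementations. Each deliberately re-derives its quantity from the
# definition with a different algorithm than the package uses.

# All-pairs O(T^3) visibility check: i and j see each other iff every
# intermediate point lies strictly below the chord.
oracle_visibility_edges <- function(x) {
  n <- length(x)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ks <- if (j - i > 1) (i + 1):(j - 1) else integer(0)
      visible <- all(x[ks] < x[j] + (x[i] - x[j]) * (j - ks) / (j - i))
      if (visible) {
        from <- c(from, i)
        to <- c(to, j)
      }
    }
  }
  cbind(from, to)
}

# Naive O(T^2) matrix-based template-match counting for the quadratic
# entropy: Chebyshev distances over all template pairs, self-matches
# excluded, both template lengths indexed over i = 1..T-m.
oracle_qe <- function(x, m, r, normalize = TRUE) {
  if (normalize) {
    s <- sd(x)
    if (s > 0) x <- (x - mean(x)) / s
  }
  n <- length(x) - m
  cheb_m <- matrix(0, n, n)
  for (k in 0:(m - 1)) {
    cheb_m <- pmax(cheb_m, abs(outer(x[(1:n) + k], x[(1:n) + k], "-")))
  }
  cheb_m1 <- pmax(cheb_m, abs(outer(x[(1:n) + m], x[(1:n) + m], "-")))
  diag(cheb_m) <- Inf
  diag(cheb_m1) <- Inf
  B <- sum(cheb_m <= r)
  A <- sum(cheb_m1 <= r)
  if (B == 0) return(NA_real_)
  -log(A / B) + log(2 * r)
}

# Direct enumeration of lag-k quantile transitions with an explicit double
# loop over bin pairs.
oracle_qg_adjacency <- function(x, q, k) {
  bins <- quantile_bins(x, q)
  n <- length(x)
  adj <- matrix(0L, q, q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      for (t in seq_len(n - k)) {
        if (bins[t] == i && bins[t + k] == j) adj[i, j] <- adj[i, j] + 1L
      }
    }
  }
  adj
}

# Leaner enumeration for larger series (still independent of tabulate()).
oracle_qg_adjacency_fast <- function(x, q, k) {
  bins <- quantile_bins(x, q)
  n <- length(x)
  adj <- matrix(0L, q, q)
  for (t in seq_len(n - k)) {
    adj[bins[t], bins[t + k]] <- adj[bins[t], bins[t + k]] + 1L
  }
  adj
}

# The full N x N analysis matrix of one periodized Daubechies-4 level,
# built row by row from explicit filter shifts; an independent check of the
# pyramid implementation and of orthogonality.
oracle_dwt_matrix <- function(n) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (j in 1:4) {
      pos <- ((2 * (k - 1) + (j - 1)) %% n) + 1
      W[k, pos] <- W[k, pos] + h[j]
      W[n / 2 + k, pos] <- W[n / 2 + k, pos] + g[j]
    }
  }
  W
}

# Eq.-1-style direct double sum for the Morlet CWT at one scale.
oracle_cwt_row <- function(x, scale, omega0 = 6) {
  n <- length(x)
  vapply(seq_len(n), function(b) {
    t <- seq_len(n)
    u <- (t - b) / scale
    psi <- pi^(-0.25) * exp(1i * omega0 * u - u^2 / 2)
    sum(x * Conj(psi)) / sqrt(scale)
  }, complex(1))
}

# Energy fraction of a series inside [f_lo, f_hi] Hz, from the periodogram.
oracle_band_energy_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  spec <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  sum(spec[freqs >= f_lo & freqs <= f_hi]) / sum(spec)
}
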