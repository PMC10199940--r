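# Scalar waveform measures: Katz fractal dimension, quadratic entropy,
# relative wavelet energy.

#' Katz fractal dimension
#'
#' Waveform complexity estimate from the curve length `D` (sum of
#' adjacent-point distances with unit abscissa steps) and the maximal distance
#' `d` from the first point: `F = ln(T - 1) / ln(d (T - 1) / D)`. Any straight
#' line has `F = 1`; more irregular waveforms score higher.
#'
#' @param x Numeric series with at least 3 points.
#' @return The fractal dimension, a scalar `>= 1` up to rounding.
#' @export
#' @examples
#' katz_fd(c(0, 1, 2, 3)) # straight line -> 1
#' katz_fd(c(0, 1, 0, 1, 0)) # 4/3
katz_fd <- function(x) {
  n <- length(x)
  if (n < 3) stop_eeg("Katz fractal dimension needs at least 3 points")
  D <- sum(sqrt(1 + diff(x)^2))
  i <- seq_len(n)
  d <- max(sqrt((i - 1)^2 + (x[1] - x)^2))
  den <- log(d * (n - 1) / D)
  if (den == 0) stop_eeg("degenerate series: d (T - 1) equals D")
  log(n - 1) / den
}

#' Quadratic entropy
#'
#' Sample-entropy variant: `E = -ln(A / B)` where `B` and `A` count Chebyshev
#' template matches within tolerance `r` at template lengths `m` and `m + 1`
#' (self-matches excluded, both lengths indexed over `i = 1..T-m`), corrected
#' to `Q = E + ln(2r)` to stabilise the tolerance dependence. By default the
#' series is z-scored first, so `r` is expressed in standard-deviation units;
#' a constant series (zero variance) is left unscaled, for which `Q = ln(2r)`
#' exactly.
#'
#' @param x Numeric series with `length(x) > m + 2`.
#' @param m Template length (the study scans `m` in 1, 2).
#' @param r Positive tolerance (the study scans `r` in 0.05..1.00 by 0.05).
#' @param normalize Z-score the series before matching (default `TRUE`).
#' @return The quadratic entropy `Q`, or `NA` (with a warning) when no
#'   length-`m` match exists and the ratio is undefined.
#' @export
#' @examples
#' quadratic_entropy(rep(1, 50), m = 1, r = 0.5) # ln(2 * 0.5) = 0
quadratic_entropy <- function(x, m = 2, r = 0.2, normalize = TRUE) {
  n <- length(x)
  if (r <= 0) stop_eeg("`r` must be positive")
  if (n <= m + 2) stop_eeg("series too short: need length > m + 2")
  if (normalize) {
    s <- sd(x)
    if (s > 0) x <- (x - mean(x)) / s
  }
  cnt <- qe_counts_cpp(as.numeric(x), as.integer(m), r)
  if (cnt[1] == 0) {
    warning("no length-m template matches; quadratic entropy undefined")
    return(NA_real_)
  }
  -log(cnt[2] / cnt[1]) + log(2 * r)
}

# All (m, r) grid values in one O(T^2) pass per m; returns a tibble
# (m, r, value). Used by parameter scans.
quadratic_entropy_grid <- function(x, m_grid = c(1, 2),
                                   r_grid = seq(0.05, 1, by = 0.05),
                                   normalize = TRUE) {
  if (normalize) {
    s <- sd(x)
    if (s > 0) x <- (x - mean(x)) / s
  }
  r_grid <- sort(r_grid)
  purrr::map_dfr(m_grid, function(m) {
    cnt <- qe_grid_counts_cpp(as.numeric(x), as.integer(m), r_grid)
    value <- ifelse(cnt[, 1] > 0, -log(cnt[, 2] / cnt[, 1]) + log(2 * r_grid),
                    NA_real_)
    tibble::tibble(m = m, r = r_grid, value = value)
  })
}

#' Relative wavelet energy of an EEG band
#'
#' Fraction of the total squared-coefficient energy of the J = 4 Daubechies-4
#' decomposition carried by the coefficient set mapped to `band`. For
#' `band = "original"` the numerator is the complete set of J + 1 coefficient
#' sets, so the ratio evaluates to 1 for every nonzero signal -- the measure
#' carries no information on unfiltered signals.
#'
#' @inheritParams extract_band
#' @return Relative energy in `[0, 1]`.
#' @export
#' @examples
#' x <- sin(2 * pi * 6 * (0:1023) / 128)
#' relative_wavelet_energy(x, "theta")
#' relative_wavelet_energy(x, "original")
relative_wavelet_energy <- function(x, band, fs = 128) {
  check_band(band)
  if (fs != 128) stop_eeg("band mapping is defined for fs = 128 Hz")
  dec <- dwt_decompose(x, levels = 4)
  e <- band_energies(dec)
  total <- sum(e)
  if (total == 0) stop_eeg("zero-energy signal")
  if (band == "original") {
    return(sum(e) / total)
  }
  set <- .BAND_SET[[band]]
  e[[if (set == "a4") "a" else set]] / total
}
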