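# Continuous Morlet wavelet transform and wavelet coherence.
#
# The transform follows C(a, b) = a^(-1/2) * sum_t x(t) Conj(psi((t - b) / a))
# evaluated as an exact (zero-padded, FFT-accelerated) discrete sum with the
# complex Morlet mother wavelet psi(u) = pi^(-1/4) exp(i w0 u) exp(-u^2 / 2),
# truncated where its envelope falls below exp(-18).
#
# Coherence needs smoothing: the pointwise modulus of Eq.-style normalised
# cross-spectra is identically 1, so cross- and auto-spectra are smoothed in
# time (Gaussian kernel with sd equal to the scale) and across scales
# (3-point boxcar) before the ratio, as in standard practice.

morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# Geometric scale grid (in samples) covering [fmin, fmax] Hz with nv voices
# per octave.
cwt_scales <- function(fs, fmin = 0.5, fmax = 30, nv = 6, omega0 = 6) {
  stopifnot(fmin > 0, fmax > fmin)
  n_oct <- log2(fmax / fmin)
  freqs <- fmax * 2^(-seq(0, n_oct, by = 1 / nv))
  fs / (freqs * morlet_fourier_factor(omega0))
}

# Linear (zero-padded) complex convolution via FFT.
fft_conv <- function(x, v) {
  n_out <- length(x) + length(v) - 1
  n <- stats::nextn(n_out, 2)
  out <- fft(fft(c(x, rep(0, n - length(x)))) *
               fft(c(v, rep(0, n - length(v)))), inverse = TRUE) / n
  out[seq_len(n_out)]
}

#' Continuous Morlet wavelet transform
#'
#' @param x Numeric series.
#' @param scales Scale grid in samples (strictly positive); defaults to a
#'   geometric grid spanning `fmin`..`fmax` Hz at `nv` voices per octave.
#' @param fs Sampling rate in Hz (used to label scales with frequencies).
#' @param fmin,fmax Frequency range covered by the default scale grid.
#' @param nv Voices per octave of the default grid.
#' @param omega0 Morlet centre frequency (rad/sample at unit scale).
#' @return A `cwt_field`: list with `coefficients` (complex scales x time
#'   matrix), `scales` (samples), `freqs` (Hz) and `omega0`.
#' @export
#' @examples
#' field <- cwt(sin(2 * pi * 10 * (0:255) / 128), nv = 2)
#' dim(field$coefficients)
cwt <- function(x, scales = NULL, fs = 128, fmin = 0.5, fmax = 30, nv = 6,
                omega0 = 6) {
  n <- length(x)
  if (is.null(scales)) scales <- cwt_scales(fs, fmin, fmax, nv, omega0)
  if (length(scales) == 0) stop_eeg("empty scale grid")
  if (any(scales <= 0)) stop_eeg("scales must be positive")
  coef <- matrix(0i, nrow = length(scales), ncol = n)
  for (s in seq_along(scales)) {
    a <- scales[s]
    L <- ceiling(6 * a)
    u <- (-L:L) / a
    psi <- pi^(-0.25) * exp(1i * omega0 * u - u^2 / 2)
    # C(b) = sum_j x[b + j] Conj(psi(j / a)) / sqrt(a): full convolution of x
    # with the reversed conjugate kernel, offset by L.
    v <- rev(Conj(psi)) / sqrt(a)
    full <- fft_conv(as.complex(x), v)
    coef[s, ] <- full[L + seq_len(n)]
  }
  structure(
    list(
      coefficients = coef, scales = scales,
      freqs = fs / (scales * morlet_fourier_factor(omega0)),
      omega0 = omega0, fs = fs
    ),
    class = "cwt_field"
  )
}

#' @export
print.cwt_field <- function(x, ...) {
  cat(
    "<cwt_field>", length(x$scales), "scales (",
    signif(min(x$freqs), 3), "-", signif(max(x$freqs), 3), "Hz ) x",
    ncol(x$coefficients), "samples\n"
  )
  invisible(x)
}

# Smooth a (possibly complex) scales x time matrix: Gaussian in time with
# per-scale sd equal to the scale, then 3-point boxcar across scales.
smooth_field <- function(m, scales) {
  out <- m
  for (s in seq_along(scales)) {
    a <- scales[s]
    L <- ceiling(3 * a)
    kern <- exp(-0.5 * ((-L:L) / a)^2)
    kern <- kern / sum(kern)
    full <- fft_conv(m[s, ], as.complex(kern))
    out[s, ] <- full[L + seq_len(ncol(m))]
  }
  if (length(scales) >= 3) {
    padded <- rbind(out[1, , drop = FALSE], out, out[nrow(out), , drop = FALSE])
    out <- (padded[seq_len(nrow(out)), , drop = FALSE] +
              padded[seq_len(nrow(out)) + 1, , drop = FALSE] +
              padded[seq_len(nrow(out)) + 2, , drop = FALSE]) / 3
  }
  out
}

#' Wavelet coherence between two series
#'
#' Frequency-resolved agreement between `x` and `y`: the modulus of the
#' smoothed cross-wavelet spectrum normalised by the smoothed auto-spectra,
#' `|S(Cx Cy*)| / sqrt(S(|Cx|^2) S(|Cy|^2))`, lying in `[0, 1]` pointwise.
#' The scalar `summary` averages the coherence map over the time-scale plane
#' restricted to `fmin`..`fmax`.
#'
#' @param x,y Numeric series of equal length, neither constant.
#' @inheritParams cwt
#' @return A `wavelet_coherence`: list with `coherence` (scales x time matrix
#'   in `[0, 1]`), `scales`, `freqs` and `summary`.
#' @export
#' @examples
#' x <- white_noise(256, seed = 1)
#' wavelet_coherence(x, x, nv = 2)$summary # self-coherence = 1
wavelet_coherence <- function(x, y, fs = 128, fmin = 0.5, fmax = 30, nv = 6,
                              omega0 = 6) {
  if (length(x) != length(y)) stop_eeg("`x` and `y` must have equal length")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_eeg("constant input: auto-spectrum is zero")
  }
  cx <- cwt(x, fs = fs, fmin = fmin, fmax = fmax, nv = nv, omega0 = omega0)
  cy <- cwt(y, scales = cx$scales, fs = fs, omega0 = omega0)
  scales <- cx$scales
  sxy <- smooth_field(cx$coefficients * Conj(cy$coefficients), scales)
  sxx <- Re(smooth_field(Mod(cx$coefficients)^2 + 0i, scales))
  syy <- Re(smooth_field(Mod(cy$coefficients)^2 + 0i, scales))
  den <- sqrt(pmax(sxx, 0) * pmax(syy, 0))
  coh <- Mod(sxy) / ifelse(den > 0, den, 1)
  coh <- pmin(coh, 1)
  structure(
    list(
      coherence = coh, scales = scales, freqs = cx$freqs,
      summary = mean(coh)
    ),
    class = "wavelet_coherence"
  )
}

#' @export
print.wavelet_coherence <- function(x, ...) {
  cat(
    "<wavelet_coherence>", nrow(x$coherence), "scales x",
    ncol(x$coherence), "samples; summary =", signif(x$summary, 4), "\n"
  )
  invisible(x)
}
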