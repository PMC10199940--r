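# Synthetic EEG cohort generator.
#
# Each channel is a weighted sum of narrowband Gaussian processes (delta,
# theta, alpha, beta) plus a 1/f-type background, synthesised in the frequency
# domain and renormalised to unit variance. The AD effect has three coupled
# components, all proportional to the effect dials and all vanishing at zero
# effect: (i) a fraction `delta_shift` of the alpha/beta spectral weight is
# moved into delta/theta, (ii) the within-delta spectrum is tilted toward its
# low edge (spectral slowing), and (iii) the whole channel is low-pass
# smoothed with a Gaussian kernel of `autocorr_boost` samples, reducing
# waveform complexity.

#' Specification of a synthetic EEG cohort
#'
#' Describes the cohort layout and effect sizes used by [generate_subject()]
#' and [generate_cohort()]. Defaults mirror the study design the package
#' targets: groups of 12 healthy and 80 AD subjects per eye condition, 19
#' channels sampled at 128 Hz for 8 s (1024 samples).
#'
#' @param n_healthy Healthy subjects per eye condition (groups A and B).
#' @param n_ad AD subjects per eye condition (groups C and D).
#' @param fs Sampling rate in Hz.
#' @param duration Segment duration in seconds; `fs * duration` must be an
#'   integer sample count.
#' @param n_channels Number of channels (at most 19; named from the canonical
#'   10-20 list).
#' @param delta_shift Effect size in `[0, 1]`: fraction of alpha/beta spectral
#'   weight moved into delta/theta for AD subjects, which also scales the
#'   within-delta 1/f tilt. Zero gives healthy-identical AD signals.
#' @param autocorr_boost Extra Gaussian smoothing (kernel standard deviation in
#'   samples) applied to AD signals; reduces signal complexity. Zero disables.
#' @param seed Integer master seed; every channel's randomness is derived from
#'   `(seed, group, subject, channel)` so generation is reproducible piecewise
#'   and independent of generation order.
#'
#' @return An object of class `eeg_cohort_spec`.
#' @export
#' @examples
#' eeg_cohort_spec(n_healthy = 2, n_ad = 2, seed = 7)
eeg_cohort_spec <- function(n_healthy = 12, n_ad = 80, fs = 128, duration = 8,
                            n_channels = 19, delta_shift = 0.4,
                            autocorr_boost = 0.5, seed = 1L) {
  if (duration <= 0) stop_eeg("`duration` must be positive")
  if (fs <= 0) stop_eeg("`fs` must be positive")
  n_samples <- fs * duration
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop_eeg("`fs * duration` must be an integer sample count")
  }
  if (n_healthy < 1 || n_ad < 1) stop_eeg("group sizes must be at least 1")
  if (n_channels < 1 || n_channels > length(.EEG_CHANNELS)) {
    stop_eeg("`n_channels` must be between 1 and ", length(.EEG_CHANNELS))
  }
  if (delta_shift < 0 || delta_shift > 1) {
    stop_eeg("`delta_shift` must be in [0, 1]")
  }
  if (autocorr_boost < 0) stop_eeg("`autocorr_boost` must be >= 0")
  structure(
    list(
      n_healthy = as.integer(n_healthy), n_ad = as.integer(n_ad),
      fs = fs, duration = duration, n_samples = as.integer(round(n_samples)),
      n_channels = as.integer(n_channels),
      channel_names = .EEG_CHANNELS[seq_len(n_channels)],
      delta_shift = delta_shift, autocorr_boost = autocorr_boost,
      seed = as.integer(seed)
    ),
    class = "eeg_cohort_spec"
  )
}

#' @export
print.eeg_cohort_spec <- function(x, ...) {
  cat(
    "<eeg_cohort_spec>", x$n_healthy, "healthy +", x$n_ad,
    "AD per eye condition;", x$n_channels, "channels,",
    x$n_samples, "samples @", x$fs, "Hz\n"
  )
  cat(
    "  delta_shift =", x$delta_shift, " autocorr_boost =", x$autocorr_boost,
    " seed =", x$seed, "\n"
  )
  invisible(x)
}

# Deterministic per-channel seed below 2^31.
channel_seed <- function(seed, group, subject_index, channel) {
  group_idx <- match(group, .EEG_GROUPS)
  offset <- group_idx * 10007L + as.integer(subject_index) * 101L +
    as.integer(channel)
  (abs(as.integer(seed)) %% 99991L) * 21001L + offset
}

# Gaussian band-limited noise from a shaped spectrum. `tilt` is the amplitude
# exponent: coefficient amplitude ~ f^(-tilt) inside [f_lo, f_hi].
spectral_noise <- function(n, fs, f_lo, f_hi, tilt = 0) {
  stopifnot(n %% 2 == 0)
  half <- n / 2
  freqs <- (1:half) * fs / n # bins 1 .. n/2 (Nyquist last)
  amp <- ifelse(freqs >= f_lo & freqs <= f_hi, freqs^(-tilt), 0)
  if (all(amp == 0)) stop_eeg("empty band [", f_lo, ", ", f_hi, "] at fs ", fs)
  z <- complex(
    real = rnorm(half) * amp,
    imaginary = c(rnorm(half - 1), 0) * c(amp[-half], 0)
  )
  spec <- c(0 + 0i, z, Conj(rev(z[-half])))
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) x else (x - mean(x)) / s
}

# Band weights (power fractions of the oscillatory part) for one subject.
band_weights <- function(group, delta_shift) {
  w <- c(delta = 0.20, theta = 0.20, alpha = 0.35, beta = 0.25)
  if (.GROUP_EYE[[group]] == "closed") {
    w["alpha"] <- w["alpha"] * 1.6
    w <- w / sum(w)
  }
  if (.GROUP_STATUS[[group]] == "ad" && delta_shift > 0) {
    moved <- delta_shift * (w[["alpha"]] + w[["beta"]])
    w["alpha"] <- w[["alpha"]] * (1 - delta_shift)
    w["beta"] <- w[["beta"]] * (1 - delta_shift)
    w["delta"] <- w[["delta"]] + 0.6 * moved
    w["theta"] <- w[["theta"]] + 0.4 * moved
  }
  w
}

synth_channel <- function(n, fs, group, delta_shift, autocorr_boost) {
  w <- band_weights(group, delta_shift)
  is_ad <- .GROUP_STATUS[[group]] == "ad"
  osc <- 0.7
  # Spectral slowing inside the delta band: AD delta power tilts toward the
  # low band edge as f^(-4 * delta_shift), vanishing at zero effect.
  delta_tilt <- if (is_ad) 2 * delta_shift else 0
  x <- sqrt(osc * w[["delta"]]) * spectral_noise(n, fs, 0.5, 4, delta_tilt) +
    sqrt(osc * w[["theta"]]) * spectral_noise(n, fs, 4, 8) +
    sqrt(osc * w[["alpha"]]) * spectral_noise(n, fs, 8, 15) +
    sqrt(osc * w[["beta"]]) * spectral_noise(n, fs, 15, 30) +
    sqrt(1 - osc) * spectral_noise(n, fs, 0.5, 30, tilt = 0.5)
  if (is_ad && autocorr_boost > 0) {
    # Gaussian low-pass: H(f) = exp(-(2 pi f sigma / fs)^2 / 2), sigma samples.
    half <- n / 2
    freqs <- c(0, (1:half) * fs / n, ((half - 1):1) * fs / n)
    h <- exp(-0.5 * (2 * pi * freqs * autocorr_boost / fs)^2)
    x <- Re(fft(fft(x) * h, inverse = TRUE)) / n
  }
  20 * (x - mean(x)) / sd(x) # microvolt scale, unit shape variance
}

#' Generate one synthetic EEG record
#'
#' Draws the multichannel record of subject `subject_index` of `group` under a
#' cohort specification. Fully reproducible: the same `(seed, group,
#' subject_index)` always yields a bit-identical record, regardless of what
#' else has been generated.
#'
#' @param spec An [eeg_cohort_spec()].
#' @param group Group label: `"A"` (healthy, eyes open), `"B"` (healthy,
#'   closed), `"C"` (AD, open) or `"D"` (AD, closed).
#' @param subject_index Positive subject counter within the group.
#' @return An `eeg_record`: list with `subject_id`, `group`, `eye_condition`,
#'   `channel_names`, `signal` (channels x samples matrix) and `fs`.
#' @export
#' @examples
#' rec <- generate_subject(eeg_cohort_spec(n_healthy = 2, n_ad = 2), "A", 1)
#' dim(rec$signal)
generate_subject <- function(spec, group, subject_index) {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  check_group(group)
  stopifnot(subject_index >= 1)
  n <- spec$n_samples
  signal <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (ch in seq_len(spec$n_channels)) {
    signal[ch, ] <- with_local_seed(
      channel_seed(spec$seed, group, subject_index, ch),
      synth_channel(n, spec$fs, group, spec$delta_shift, spec$autocorr_boost)
    )
  }
  rownames(signal) <- spec$channel_names
  new_eeg_record(
    subject_id = sprintf("%s%02d", group, subject_index),
    group = group,
    channel_names = spec$channel_names,
    signal = signal,
    fs = spec$fs
  )
}

#' Generate a full synthetic cohort
#'
#' Generates `n_healthy` records for each of groups A and B and `n_ad` records
#' for each of groups C and D, with unique subject identifiers.
#'
#' @inheritParams generate_subject
#' @return A list of `eeg_record` objects with the spec attached as attribute
#'   `"spec"`.
#' @export
#' @examples
#' cohort <- generate_cohort(eeg_cohort_spec(n_healthy = 1, n_ad = 1))
#' length(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  sizes <- c(A = spec$n_healthy, B = spec$n_healthy,
             C = spec$n_ad, D = spec$n_ad)
  records <- list()
  for (g in .EEG_GROUPS) {
    for (i in seq_len(sizes[[g]])) {
      records[[length(records) + 1L]] <- generate_subject(spec, g, i)
    }
  }
  attr(records, "spec") <- spec
  records
}

#' Gaussian white noise
#'
#' Independent standard-normal draws, reproducible from `seed`; used by the
#' computational-cost benchmark and by null-calibration tests.
#'
#' @param n Series length (at least 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' white_noise(5, seed = 1)
white_noise <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_eeg("`n` must be a positive length")
  }
  with_local_seed(seed, rnorm(as.integer(n)))
}
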