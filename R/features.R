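# Tabular feature extraction: one row per (subject, electrode/pair, band,
# measure, parameter tuple).
#
# Measure codes follow the field's shorthand:
#   wc -- wavelet coherence (electrode pairs)
#   fd -- Katz fractal dimension
#   qe -- quadratic entropy (parameters m, r)
#   we -- relative wavelet energy
#   qg -- quantile-graph mean jump length (parameters q, k)
#   vg -- visibility-graph complexity index

.EEG_MEASURES <- c("wc", "fd", "qe", "we", "qg", "vg")

# Frequency range used when summarising coherence of a band-filtered pair.
band_freq_range <- function(band) {
  switch(band,
    original = c(0.5, 30), beta = c(16, 30), alpha = c(8, 16),
    theta = c(4, 8), delta = c(0.5, 4)
  )
}

check_measures <- function(measures) {
  bad <- setdiff(measures, .EEG_MEASURES)
  if (length(bad) > 0) {
    stop_eeg(
      "unknown measures: ", paste(bad, collapse = ", "),
      " (expected among ", paste(.EEG_MEASURES, collapse = ", "), ")"
    )
  }
  measures
}

all_electrode_pairs <- function(channels) {
  pairs <- utils::combn(channels, 2)
  paste(pairs[1, ], pairs[2, ], sep = "-")
}

feature_row <- function(electrode, band, measure, value,
                        m = NA_real_, r = NA_real_,
                        q = NA_real_, k = NA_real_) {
  tibble::tibble(
    electrode = electrode, band = band, measure = measure,
    m = m, r = r, q = q, k = k, value = value
  )
}

# All requested single-channel measures for one channel and band. `x` is the
# band-filtered series; `raw` the unfiltered channel (the relative wavelet
# energy is a coefficient-set ratio of the raw signal, not of the filtered
# one -- filtering first would make it identically ~1).
channel_features <- function(x, raw, electrode, band, measures,
                             qe_m, qe_r, qg_q, qg_k) {
  out <- list()
  if ("fd" %in% measures) {
    out[[length(out) + 1L]] <- feature_row(electrode, band, "fd", katz_fd(x))
  }
  if ("we" %in% measures) {
    out[[length(out) + 1L]] <- feature_row(
      electrode, band, "we", relative_wavelet_energy(raw, band)
    )
  }
  if ("qe" %in% measures) {
    grid <- quadratic_entropy_grid(x, m_grid = qe_m, r_grid = qe_r)
    out[[length(out) + 1L]] <- feature_row(
      electrode, band, "qe", grid$value, m = grid$m, r = grid$r
    )
  }
  if ("qg" %in% measures) {
    qv <- qg_q %||% default_quantile_count(length(x))
    for (qq in qv) {
      for (kk in qg_k) {
        out[[length(out) + 1L]] <- feature_row(
          electrode, band, "qg",
          mean_jump_length(build_quantile_graph(x, q = qq, k = kk)),
          q = qq, k = kk
        )
      }
    }
  }
  if ("vg" %in% measures) {
    out[[length(out) + 1L]] <- feature_row(
      electrode, band, "vg", complexity_index(build_visibility_graph(x))
    )
  }
  dplyr::bind_rows(out)
}

#' Compute the measure table for a set of EEG records
#'
#' Evaluates the requested measures on the requested bands of every record and
#' returns one tidy row per (subject, electrode or electrode pair, band,
#' measure, parameter tuple). Parameter grids are accepted for the quadratic
#' entropy (`qe_m`, `qe_r`) and the quantile graph (`qg_q`, `qg_k`); the
#' remaining measures are parameter free. Wavelet coherence (`"wc"`) is
#' evaluated on electrode pairs (`"T3-O2"` style labels) and its scalar
#' summary is restricted to the band's frequency range.
#'
#' @param records List of `eeg_record` objects (e.g. from
#'   [generate_cohort()] or [load_cohort()]).
#' @param measures Measure codes among `wc, fd, qe, we, qg, vg`.
#' @param bands Bands among `original, beta, alpha, theta, delta`.
#' @param electrodes Channels to evaluate (default: all channels present).
#' @param pairs Electrode pairs for `wc` (default: all pairs of `electrodes`).
#' @param qe_m,qe_r Quadratic-entropy parameter grids.
#' @param qg_q Quantile counts (default: the `2 T^(1/3)` rule).
#' @param qg_k Transition lags.
#' @param nv Voices per octave for coherence.
#' @return A tibble with columns `subject_id`, `group`, `eye_condition`,
#'   `electrode`, `band`, `measure`, `m`, `r`, `q`, `k`, `value`.
#' @export
#' @examples
#' cohort <- generate_cohort(eeg_cohort_spec(n_healthy = 1, n_ad = 1))
#' compute_features(cohort, measures = "fd", bands = "original",
#'                  electrodes = "Cz")
compute_features <- function(records,
                             measures = c("fd", "qe", "we", "qg", "vg"),
                             bands = "original",
                             electrodes = NULL, pairs = NULL,
                             qe_m = 2, qe_r = 0.2,
                             qg_q = NULL, qg_k = 1,
                             nv = 6) {
  check_measures(measures)
  for (b in bands) check_band(b)
  stopifnot(length(records) > 0)
  out <- vector("list", length(records))
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    stopifnot(inherits(rec, "eeg_record"))
    chans <- electrodes %||% rec$channel_names
    missing <- setdiff(chans, rec$channel_names)
    if (length(missing) > 0) {
      stop_eeg(
        "record ", rec$subject_id, " lacks channels: ",
        paste(missing, collapse = ", ")
      )
    }
    rec_rows <- list()
    for (band in bands) {
      filtered <- lapply(
        setNames(chans, chans),
        function(ch) extract_band(rec$signal[ch, ], band, fs = rec$fs)
      )
      single <- setdiff(measures, "wc")
      if (length(single) > 0) {
        for (ch in chans) {
          rec_rows[[length(rec_rows) + 1L]] <- channel_features(
            filtered[[ch]], rec$signal[ch, ], ch, band, single,
            qe_m, qe_r, qg_q, qg_k
          )
        }
      }
      if ("wc" %in% measures) {
        use_pairs <- pairs %||% all_electrode_pairs(chans)
        fr <- band_freq_range(band)
        for (pr in use_pairs) {
          ends <- strsplit(pr, "-", fixed = TRUE)[[1]]
          if (length(ends) != 2 || !all(ends %in% rec$channel_names)) {
            stop_eeg("invalid electrode pair '", pr, "'")
          }
          sig <- lapply(ends, function(ch) {
            extract_band(rec$signal[ch, ], band, fs = rec$fs)
          })
          coh <- wavelet_coherence(
            sig[[1]], sig[[2]],
            fs = rec$fs, fmin = fr[1], fmax = fr[2], nv = nv
          )
          rec_rows[[length(rec_rows) + 1L]] <-
            feature_row(pr, band, "wc", coh$summary)
        }
      }
    }
    out[[ri]] <- dplyr::mutate(
      dplyr::bind_rows(rec_rows),
      subject_id = rec$subject_id, group = rec$group,
      eye_condition = rec$eye_condition,
      .before = 1
    )
  }
  dplyr::bind_rows(out)
}

#' Per-electrode coherence features from pair features
#'
#' Collapses wavelet-coherence pair rows onto electrodes: each electrode's
#' value is the mean pair summary over all pairs containing it. Pairwise rows
#' are what best-pair reporting uses; the electrode collapse feeds
#' electrode-level maps.
#'
#' @param features A [compute_features()] table containing `measure == "wc"`
#'   rows.
#' @return A tibble in the same shape with `electrode` holding single
#'   channels.
#' @export
coherence_electrode_means <- function(features) {
  wc <- dplyr::filter(features, .data$measure == "wc")
  if (nrow(wc) == 0) stop_eeg("no wavelet-coherence rows in `features`")
  ends <- strsplit(wc$electrode, "-", fixed = TRUE)
  long <- dplyr::bind_rows(
    dplyr::mutate(wc, electrode = vapply(ends, `[`, "", 1)),
    dplyr::mutate(wc, electrode = vapply(ends, `[`, "", 2))
  )
  dplyr::summarise(
    long,
    value = mean(.data$value),
    .by = c("subject_id", "group", "eye_condition", "electrode", "band",
            "measure", "m", "r", "q", "k")
  )
}
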