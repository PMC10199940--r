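# Computational-cost experiment: wall-time of each measure on white noise as
# a function of series length, normalised by the time at the first grid
# point. Absolute times are hardware dependent; the designed readout is the
# relative growth (and its log-log scaling exponent) across measures.

#' Default series-length grid for the cost experiment
#'
#' @param t_min,t_max,step Grid bounds and increment; the default
#'   500..10,000 by 100 has 96 points.
#' @return Integer vector of series lengths.
#' @export
#' @examples
#' length(benchmark_grid())
benchmark_grid <- function(t_min = 500, t_max = 10000, step = 100) {
  as.integer(seq.int(t_min, t_max, by = step))
}

measure_runner <- function(measure, qe_m, qe_r, qg_k, nv) {
  switch(measure,
    fd = function(x, x2) katz_fd(x),
    qe = function(x, x2) quadratic_entropy(x, m = qe_m, r = qe_r),
    we = function(x, x2) {
      n16 <- 16L * (length(x) %/% 16L)
      relative_wavelet_energy(x[seq_len(n16)], "delta")
    },
    qg = function(x, x2) mean_jump_length(build_quantile_graph(x, k = qg_k)),
    vg = function(x, x2) complexity_index(build_visibility_graph(x)),
    wc = function(x, x2) wavelet_coherence(x, x2, nv = nv)$summary,
    stop_eeg("measure not registered: ", measure)
  )
}

# Per-evaluation elapsed time; very fast calls are looped until the total is
# measurable so the normalised curve is not quantised by timer resolution.
time_one <- function(fun, x, x2, min_elapsed = 0.005) {
  t0 <- unname(system.time(fun(x, x2))["elapsed"])
  if (t0 >= min_elapsed) {
    return(t0)
  }
  reps <- ceiling(min_elapsed / max(t0, 1e-5))
  tt <- unname(system.time(for (i in seq_len(reps)) fun(x, x2))["elapsed"])
  max(tt / reps, 1e-7) # clock-resolution floor keeps log-log fits finite
}

#' Computational-cost curves of the measures
#'
#' Times each measure on fresh Gaussian white noise (coherence on two
#' independent series) at every length of `t_grid`, taking the median over
#' `repeats` runs, and normalises each curve by its value at the first grid
#' point. Parameters are held fixed while timing: m = 2 and r = 0.2 for the
#' quadratic entropy, Q = round(2 T^(1/3)) with k = 1 for the quantile graph.
#'
#' @param measures Measure codes to time.
#' @param t_grid Series lengths (default [benchmark_grid()], the 96-point
#'   500..10,000 grid).
#' @param repeats Timing repeats per point (median taken; at least 1).
#' @param seed Seed for the white-noise inputs.
#' @param qe_m,qe_r,qg_k,nv Measure parameters held fixed while timing.
#' @return An `eeg_cost_curves` tibble: `measure`, `n`, `time` (seconds,
#'   median), `time_normalized`; log-log scaling exponents via [glance()].
#' @export
#' @examples
#' \donttest{
#' curves <- cost_curve(c("fd", "qg"), t_grid = c(500, 1000), repeats = 1)
#' glance(curves)
#' }
cost_curve <- function(measures = c("wc", "fd", "qe", "we", "qg", "vg"),
                       t_grid = benchmark_grid(), repeats = 3, seed = 1L,
                       qe_m = 2, qe_r = 0.2, qg_k = 1, nv = 6) {
  check_measures(measures)
  if (repeats < 1) stop_eeg("`repeats` must be at least 1")
  stopifnot(length(t_grid) >= 1)
  rows <- list()
  counter <- 0L
  for (measure in measures) {
    fun <- measure_runner(measure, qe_m, qe_r, qg_k, nv)
    times <- numeric(length(t_grid))
    for (ti in seq_along(t_grid)) {
      n <- t_grid[ti]
      reps <- numeric(repeats)
      for (rep in seq_len(repeats)) {
        counter <- counter + 2L
        x <- white_noise(n, seed = seed + counter)
        x2 <- white_noise(n, seed = seed + counter + 1L)
        reps[rep] <- time_one(fun, x, x2)
      }
      times[ti] <- stats::median(reps)
    }
    rows[[measure]] <- tibble::tibble(
      measure = measure, n = as.integer(t_grid), time = times,
      time_normalized = times / times[1]
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eeg_cost_curves", class(out))
  out
}

#' @rdname cost_curve
#' @param x An `eeg_cost_curves` table.
#' @param ... Unused.
#' @return For `glance()`: one row per measure with the fitted log-log
#'   scaling exponent of time against series length.
#' @method glance eeg_cost_curves
#' @export
glance.eeg_cost_curves <- function(x, ...) {
  dplyr::summarise(
    tibble::as_tibble(x),
    exponent = if (dplyr::n() >= 2) {
      unname(stats::coef(stats::lm(log(.data$time) ~ log(.data$n)))[2])
    } else {
      NA_real_
    },
    time_max = .data$time[which.max(.data$n)],
    normalized_max = .data$time_normalized[which.max(.data$n)],
    .by = "measure"
  )
}
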