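# Group-discrimination screening: one-way ANOVA p values, rank-based AUC,
# parameter-grid scans, per-electrode summaries.
#
# p values are reported raw, matching the screening protocol (one value per
# electrode and grid point, no multiple-testing correction); treat small p
# values across many electrodes accordingly.

#' One-way ANOVA p value for two groups
#'
#' Fixed-effects one-way ANOVA F statistic and its upper-tail p value. With
#' two groups this is equivalent to the two-sided pooled-variance t test.
#'
#' @param values1,values2 Numeric vectors, each of length at least 2.
#' @return p value in `(0, 1]` (0 only in the degenerate case of perfect
#'   separation with zero within-group variance).
#' @export
#' @examples
#' anova_p(c(1, 2), c(3, 4)) # F = 8, p ~= 0.1056
anova_p <- function(values1, values2) {
  n1 <- length(values1)
  n2 <- length(values2)
  if (n1 < 2 || n2 < 2) stop_eeg("each group needs at least 2 values")
  all_values <- c(values1, values2)
  grand <- mean(all_values)
  ssb <- n1 * (mean(values1) - grand)^2 + n2 * (mean(values2) - grand)^2
  ssw <- sum((values1 - mean(values1))^2) + sum((values2 - mean(values2))^2)
  if (ssb == 0 && ssw == 0) {
    stop_eeg("zero within- and between-group variance")
  }
  df2 <- n1 + n2 - 2
  if (ssw == 0) {
    return(0)
  }
  f <- ssb / (ssw / df2)
  pf(f, 1, df2, lower.tail = FALSE)
}

#' Oriented rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic (ties
#' count one half), then oriented as `max(AUC, 1 - AUC)`: either direction of
#' separation marks a discriminative feature, so the reported value lies in
#' `[0.5, 1]`.
#'
#' @param values1,values2 Nonempty numeric vectors.
#' @param orient Apply the `max(AUC, 1 - AUC)` rule (default `TRUE`).
#' @return AUC in `[0.5, 1]` (in `[0, 1]` when `orient = FALSE`, measuring
#'   the probability that a draw from `values2` exceeds one from `values1`).
#' @export
#' @examples
#' auc(c(1, 2, 3), c(4, 5, 6)) # perfect separation -> 1
#' auc(c(1, 3), c(2, 4)) # 0.75
auc <- function(values1, values2, orient = TRUE) {
  n1 <- length(values1)
  n2 <- length(values2)
  if (n1 == 0 || n2 == 0) stop_eeg("both groups must be nonempty")
  rk <- rank(c(values1, values2), ties.method = "average")
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  a <- 1 - u / (n1 * n2) # P(draw from group 2 > draw from group 1)
  if (orient) max(a, 1 - a) else a
}

check_group_pair <- function(groups) {
  if (length(groups) != 2 || !all(groups %in% .EEG_GROUPS)) {
    stop_eeg("`groups` must name two of A, B, C, D")
  }
  if (.GROUP_EYE[[groups[1]]] != .GROUP_EYE[[groups[2]]]) {
    stop_eeg(
      "comparisons never mix eye conditions: use A vs C or B vs D"
    )
  }
  if (.GROUP_STATUS[[groups[1]]] == .GROUP_STATUS[[groups[2]]]) {
    stop_eeg("`groups` must pair one healthy with one AD group")
  }
  groups
}

#' Screen features for group separation
#'
#' For every (electrode, band, measure, parameter tuple) key in a
#' [compute_features()] table, computes the ANOVA p value and oriented AUC
#' between the two groups of a pair sharing one eye condition (A vs C or
#' B vs D).
#'
#' @param features A [compute_features()] tibble.
#' @param groups Group pair, `c("A", "C")` (eyes open) or `c("B", "D")`
#'   (eyes closed).
#' @return A tibble with the key columns plus `group1`, `group2`, `n1`, `n2`,
#'   `p` and `auc`, ordered by `p`.
#' @export
evaluate_features <- function(features, groups = c("A", "C")) {
  check_group_pair(groups)
  sub <- dplyr::filter(features, .data$group %in% groups, is.finite(.data$value))
  if (nrow(sub) == 0) stop_eeg("no finite feature values for these groups")
  # A key that is constant across all subjects (the relative wavelet energy
  # of unfiltered signals is identically 1) carries no evidence: p = 1.
  safe_p <- function(v1, v2) {
    if (sd(c(v1, v2)) == 0) 1 else anova_p(v1, v2)
  }
  out <- dplyr::summarise(
    sub,
    group1 = groups[1], group2 = groups[2],
    n1 = sum(.data$group == groups[1]),
    n2 = sum(.data$group == groups[2]),
    p = safe_p(
      .data$value[.data$group == groups[1]],
      .data$value[.data$group == groups[2]]
    ),
    auc = auc(
      .data$value[.data$group == groups[1]],
      .data$value[.data$group == groups[2]]
    ),
    .by = c("electrode", "band", "measure", "m", "r", "q", "k")
  )
  dplyr::arrange(out, .data$p)
}

#' Scan a measure's parameter grid for the best group separation
#'
#' Evaluates the measure at every grid point on one electrode (or electrode
#' pair) and band, and returns the point with the lowest ANOVA p value, ties
#' broken toward the lexically smallest parameter tuple. Default grids follow
#' the screening protocol: quadratic entropy over `m` in 1, 2 and `r` in
#' 0.05..1.00 by 0.05; quantile graphs at `Q = 20` with `k` in 1..25; the
#' other measures are parameter free.
#'
#' @param records List of `eeg_record` objects.
#' @param measure One measure code.
#' @param band One band name.
#' @param electrode Channel name, or `"X-Y"` pair label for `wc`.
#' @param groups Group pair (A vs C or B vs D).
#' @param qe_m,qe_r,qg_q,qg_k Parameter grids.
#' @param nv Voices per octave for coherence.
#' @return An `eeg_scan`: list with `best` (one-row tibble) and `grid` (full
#'   grid table ordered by p).
#' @export
scan_parameters <- function(records, measure, band, electrode,
                            groups = c("A", "C"),
                            qe_m = c(1, 2), qe_r = seq(0.05, 1, by = 0.05),
                            qg_q = 20, qg_k = 1:25, nv = 6) {
  check_measures(measure)
  stopifnot(length(measure) == 1)
  check_group_pair(groups)
  is_pair <- grepl("-", electrode, fixed = TRUE)
  features <- compute_features(
    Filter(function(r) r$group %in% groups, records),
    measures = measure, bands = band,
    electrodes = if (is_pair) NULL else electrode,
    pairs = if (is_pair) electrode else NULL,
    qe_m = qe_m, qe_r = qe_r, qg_q = qg_q, qg_k = qg_k, nv = nv
  )
  if (is_pair) {
    features <- dplyr::filter(features, .data$electrode == !!electrode)
  }
  grid <- evaluate_features(features, groups)
  if (nrow(grid) == 0) stop_eeg("empty parameter grid")
  best <- dplyr::arrange(grid, .data$p, .data$m, .data$r, .data$q, .data$k)[1, ]
  structure(list(best = best, grid = grid), class = "eeg_scan")
}

#' @export
print.eeg_scan <- function(x, ...) {
  cat("<eeg_scan>", nrow(x$grid), "grid points; best:\n")
  print(x$best)
  invisible(x)
}

#' @rdname scan_parameters
#' @param x An `eeg_scan`.
#' @param ... Unused.
#' @method tidy eeg_scan
#' @export
tidy.eeg_scan <- function(x, ...) x$grid

#' @rdname scan_parameters
#' @method glance eeg_scan
#' @export
glance.eeg_scan <- function(x, ...) x$best

#' Per-electrode summary of group comparisons
#'
#' Checks that every expected electrode is present exactly once, and returns
#' the per-electrode (p, AUC) table together with the arithmetic mean p value
#' over electrodes -- the map-level summary used to compare measures.
#'
#' @param comparisons An [evaluate_features()] tibble with one row per
#'   electrode (single measure, band and parameter tuple).
#' @param electrodes Expected electrode set (default: the canonical 19).
#' @return An `electrode_summary`: list with `table` (electrode, p, auc) and
#'   `average_p`.
#' @export
electrode_summary <- function(comparisons, electrodes = eeg_channels()) {
  missing <- setdiff(electrodes, comparisons$electrode)
  if (length(missing) > 0) {
    stop_eeg("missing electrodes: ", paste(missing, collapse = ", "))
  }
  tab <- dplyr::filter(comparisons, .data$electrode %in% electrodes)
  if (anyDuplicated(tab$electrode)) {
    stop_eeg("more than one comparison per electrode; filter to one key")
  }
  tab <- dplyr::arrange(
    dplyr::select(tab, "electrode", "p", "auc"),
    match(.data$electrode, electrodes)
  )
  structure(
    list(table = tab, average_p = mean(tab$p)),
    class = "electrode_summary"
  )
}

#' @export
print.electrode_summary <- function(x, ...) {
  cat(
    "<electrode_summary>", nrow(x$table), "electrodes; average p =",
    signif(x$average_p, 4), "\n"
  )
  invisible(x)
}

#' @rdname electrode_summary
#' @param x An `electrode_summary`.
#' @param ... Unused.
#' @method tidy electrode_summary
#' @export
tidy.electrode_summary <- function(x, ...) x$table

#' @rdname electrode_summary
#' @method glance electrode_summary
#' @export
glance.electrode_summary <- function(x, ...) {
  tibble::tibble(average_p = x$average_p, n_electrodes = nrow(x$table))
}
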