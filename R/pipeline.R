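# End-to-end orchestration: cohort -> band extraction -> feature table ->
# group screening with parameter scans -> best-per-measure table -> SVM
# classification, as a pure function of (input data, config).

#' Pipeline configuration
#'
#' Collects everything a [run_pipeline()] call depends on. Group pairs are
#' restricted to the two same-eye-condition comparisons (A vs C, B vs D);
#' cross-condition pairs are rejected.
#'
#' @param cohort An [eeg_cohort_spec()] (cohort is generated) or a directory
#'   path readable by [load_cohort()].
#' @param measures Measure codes to screen.
#' @param bands Bands to screen.
#' @param group_pairs List of group pairs; each must share one eye condition.
#' @param electrodes Channels to use (default: all in the cohort).
#' @param coherence_pairs Electrode pairs for `wc` (default: all pairs of the
#'   chosen electrodes; a subset keeps the coherence stage affordable).
#' @param qe_m_grid,qe_r_grid,qg_q,qg_k_grid Parameter grids (defaults: the
#'   screening protocol's `m` in 1, 2, `r` in 0.05..1 by 0.05, `Q = 20`,
#'   `k` in 1..25).
#' @param nv Voices per octave for coherence.
#' @param k_folds Cross-validation folds for the classification stage.
#' @param seed Integer seed recorded in all outputs.
#' @param out_dir Optional directory to write tab-delimited result tables to.
#' @return An `eeg_pipeline_config`.
#' @export
pipeline_config <- function(cohort = eeg_cohort_spec(),
                            measures = c("fd", "qe", "we", "qg", "vg"),
                            bands = c("original", "beta", "alpha", "theta",
                                      "delta"),
                            group_pairs = list(c("A", "C"), c("B", "D")),
                            electrodes = NULL, coherence_pairs = NULL,
                            qe_m_grid = c(1, 2),
                            qe_r_grid = seq(0.05, 1, by = 0.05),
                            qg_q = 20, qg_k_grid = 1:25,
                            nv = 6, k_folds = 10, seed = 1L,
                            out_dir = NULL) {
  check_measures(measures)
  for (b in bands) check_band(b)
  for (gp in group_pairs) check_group_pair(gp)
  if (!inherits(cohort, "eeg_cohort_spec") &&
      !(is.character(cohort) && length(cohort) == 1)) {
    stop_eeg("`cohort` must be an eeg_cohort_spec or a directory path")
  }
  structure(
    list(
      cohort = cohort, measures = measures, bands = bands,
      group_pairs = group_pairs, electrodes = electrodes,
      coherence_pairs = coherence_pairs,
      qe_m_grid = qe_m_grid, qe_r_grid = qe_r_grid,
      qg_q = qg_q, qg_k_grid = qg_k_grid,
      nv = nv, k_folds = as.integer(k_folds), seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "eeg_pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_eeg("pipeline stage '", stage, "': ", conditionMessage(e))
  })
}

#' Run the screening and classification pipeline
#'
#' Executes the full protocol: obtain the cohort, compute the feature table
#' over all measures, bands and parameter grids, screen every key with ANOVA
#' p and AUC for each group pair, reduce to a best-per-measure table (lowest
#' p, ties toward the lexically smallest parameter tuple), and classify
#' subjects with a stratified K-fold SVM on each best feature (AD groups
#' positive). Reruns with an identical config produce identical results.
#'
#' @param config An [eeg_pipeline_config][pipeline_config()].
#' @return An `eeg_pipeline_result`: list with `features`, `evaluations`,
#'   `best` (one row per measure and group pair: electrode, band, parameters,
#'   p, AUC), `classification` (adds Acc/Sen/Spe and confusion counts),
#'   `config` and `provenance`. If `config$out_dir` is set, the three result
#'   tables are also written as tab-delimited files with provenance headers.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   cohort = eeg_cohort_spec(n_healthy = 4, n_ad = 4, n_channels = 3),
#'   measures = c("fd", "we"), bands = c("original", "delta"),
#'   group_pairs = list(c("A", "C")), k_folds = 4
#' )
#' res <- run_pipeline(cfg)
#' res$best
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  records <- pipeline_stage("cohort", {
    if (inherits(config$cohort, "eeg_cohort_spec")) {
      generate_cohort(config$cohort)
    } else {
      load_cohort(config$cohort)$records
    }
  })
  features <- pipeline_stage("features", compute_features(
    records,
    measures = config$measures, bands = config$bands,
    electrodes = config$electrodes, pairs = config$coherence_pairs,
    qe_m = config$qe_m_grid, qe_r = config$qe_r_grid,
    qg_q = config$qg_q, qg_k = config$qg_k_grid, nv = config$nv
  ))
  evaluations <- pipeline_stage("evaluation", dplyr::bind_rows(
    lapply(config$group_pairs, function(gp) evaluate_features(features, gp))
  ))
  best <- pipeline_stage("best", {
    dplyr::slice_head(
      dplyr::arrange(
        evaluations,
        .data$p, .data$band, .data$electrode, .data$m, .data$r, .data$q,
        .data$k
      ),
      n = 1, by = c("measure", "group1", "group2")
    ) |>
      dplyr::arrange(
        match(.data$measure, .EEG_MEASURES), .data$group1
      )
  })
  classification <- pipeline_stage("classification", {
    dplyr::bind_rows(lapply(seq_len(nrow(best)), function(i) {
      key <- best[i, ]
      vals <- dplyr::filter(
        features,
        .data$measure == key$measure, .data$electrode == key$electrode,
        .data$band == key$band,
        (is.na(key$m) | .data$m %in% key$m), (is.na(key$r) | .data$r %in% key$r),
        (is.na(key$q) | .data$q %in% key$q), (is.na(key$k) | .data$k %in% key$k),
        .data$group %in% c(key$group1, key$group2)
      )
      d <- data.frame(
        value = vals$value,
        label = ifelse(.GROUP_STATUS[vals$group] == "ad", "AD", "healthy")
      )
      rep <- kfold_svm(
        d, positive = "AD", k = config$k_folds, seed = config$seed
      )
      dplyr::bind_cols(key, glance(rep)[c(
        "accuracy", "sensitivity", "specificity", "tp", "fn", "tn", "fp"
      )])
    }))
  })
  result <- structure(
    list(
      features = features, evaluations = evaluations, best = best,
      classification = classification, config = config,
      provenance = list(
        package_version = as.character(utils::packageVersion("eegmarkers")),
        seed = config$seed, config_hash = config_hash(config)
      )
    ),
    class = "eeg_pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_result(result, config$out_dir)
  }
  result
}

write_result_table <- function(tab, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# eegmarkers", provenance$package_version),
    paste("# seed", provenance$seed),
    paste("# config", provenance$config_hash),
    "# note: p values are raw; no multiple-testing correction is applied"
  ), con)
  utils::write.table(
    as.data.frame(tab), con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- result$provenance
  write_result_table(
    result$evaluations, file.path(out_dir, "evaluations.tsv"), prov
  )
  write_result_table(result$best, file.path(out_dir, "best.tsv"), prov)
  write_result_table(
    result$classification, file.path(out_dir, "classification.tsv"), prov
  )
  invisible(out_dir)
}

#' @export
print.eeg_pipeline_result <- function(x, ...) {
  cat(
    "<eeg_pipeline_result>", nrow(x$features), "feature rows;",
    nrow(x$evaluations), "screened keys\n"
  )
  cat("best per measure:\n")
  print(dplyr::select(
    x$best, "measure", "electrode", "band", "group1", "group2", "p", "auc"
  ))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `eeg_pipeline_result`.
#' @param ... Unused.
#' @return For `tidy()`: the best-per-measure screening table; for
#'   `glance()`: the classification table (best key plus Acc/Sen/Spe).
#' @method tidy eeg_pipeline_result
#' @export
tidy.eeg_pipeline_result <- function(x, ...) x$best

#' @rdname run_pipeline
#' @method glance eeg_pipeline_result
#' @export
glance.eeg_pipeline_result <- function(x, ...) x$classification
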