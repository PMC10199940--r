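test_that("the two-group ANOVA matches hand computation", {
  # SSB = 4, SSW = 1, F = 8 on df (1, 2)
  expect_equal(anova_p(c(1, 2), c(3, 4)), pf(8, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(anova_p(c(1, 2), c(3, 4)), 0.10557, tolerance = 1e-4)
  expect_equal(anova_p(c(0, 1), c(0, 1)), 1.0)
  # scale invariance of F
  expect_equal(anova_p(10 * c(1, 2), 10 * c(3, 4)), anova_p(c(1, 2), c(3, 4)),
               tolerance = 1e-12)
  expect_error(anova_p(1, c(2, 3)), "at least 2")
  expect_error(anova_p(c(1, 1), c(1, 1)), "zero within- and between")
})

test_that("the rank AUC handles separation, interleaving and orientation", {
  expect_equal(auc(c(1, 2, 3), c(4, 5, 6)), 1.0)
  expect_equal(auc(c(1, 3), c(2, 4)), 0.75)
  # orientation symmetry
  x <- white_noise(30, seed = 1)
  y <- white_noise(25, seed = 2) + 0.3
  expect_equal(auc(x, y), auc(y, x), tolerance = 1e-12)
  expect_equal(auc(x, y, orient = FALSE), 1 - auc(y, x, orient = FALSE),
               tolerance = 1e-12)
  # null value with many draws
  a <- white_noise(10000, seed = 3)
  b <- white_noise(10000, seed = 4)
  expect_equal(auc(a, b), 0.5, tolerance = 0.02)
  expect_error(auc(numeric(0), 1:3), "nonempty")
})

test_that("feature screening computes one comparison per key", {
  cohort <- generate_cohort(
    eeg_cohort_spec(n_healthy = 5, n_ad = 5, n_channels = 2,
                    delta_shift = 0.8, seed = 21)
  )
  feats <- compute_features(cohort, measures = c("fd", "we"),
                            bands = c("original", "delta"))
  ev <- evaluate_features(feats, c("A", "C"))
  expect_identical(nrow(ev), 2L * 2L * 2L) # 2 electrodes x 2 bands x 2 measures
  expect_true(all(ev$p > 0 & ev$p <= 1))
  expect_true(all(ev$auc >= 0.5 & ev$auc <= 1))
  expect_identical(unique(ev$n1), 5L)
  expect_error(evaluate_features(feats, c("A", "D")), "mix eye conditions")
  expect_error(evaluate_features(feats, c("A", "A")), "healthy with one AD")
})

test_that("parameter scans return the lowest-p grid point with lexical ties", {
  cohort <- generate_cohort(
    eeg_cohort_spec(n_healthy = 8, n_ad = 8, n_channels = 1,
                    delta_shift = 0.8, seed = 22)
  )
  scan <- scan_parameters(
    cohort, "qg", "delta", "Fp1",
    groups = c("A", "C"), qg_q = 20, qg_k = 1:5
  )
  expect_identical(nrow(scan$grid), 5L)
  expect_equal(scan$best$p, min(scan$grid$p))
  expect_identical(tidy(scan), scan$grid)
  # single-point grid returns that point
  one <- scan_parameters(cohort, "fd", "original", "Fp1",
                         groups = c("A", "C"))
  expect_identical(nrow(one$grid), 1L)
  # lexical tie-breaking among equal-p grid points
  ev <- tibble::tibble(
    electrode = "Fp1", band = "delta", measure = "qg",
    m = NA_real_, r = NA_real_, q = 20, k = c(3, 1, 2),
    group1 = "A", group2 = "C", n1 = 8L, n2 = 8L,
    p = c(0.2, 0.2, 0.5), auc = c(0.8, 0.8, 0.6)
  )
  best <- dplyr::arrange(ev, p, m, r, q, k)[1, ]
  expect_identical(best$k, 1)
})

test_that("electrode summaries average p and flag missing electrodes", {
  tab <- tibble::tibble(
    electrode = eeg_channels(), p = 0.05, auc = 0.7
  )
  s <- electrode_summary(tab)
  expect_equal(s$average_p, 0.05)
  expect_identical(nrow(tidy(s)), 19L)
  expect_equal(glance(s)$n_electrodes, 19L)
  expect_error(electrode_summary(tab[-3, ]), "F3")
})
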