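test_that("generated records have the declared shape and metadata", {
  spec <- eeg_cohort_spec(n_healthy = 2, n_ad = 2, seed = 42)
  rec <- generate_subject(spec, "A", 1)
  expect_s3_class(rec, "eeg_record")
  expect_identical(dim(rec$signal), c(19L, 1024L))
  expect_identical(rec$channel_names, eeg_channels())
  expect_identical(rec$eye_condition, "open")
  rec_d <- generate_subject(spec, "D", 1)
  expect_identical(rec_d$eye_condition, "closed")
  expect_false(anyNA(rec$signal))
  # channels are standardised to a fixed microvolt scale
  expect_equal(unname(apply(rec$signal, 1, sd)), rep(20, 19), tolerance = 1e-12)
})

test_that("generation is deterministic and order independent", {
  spec <- eeg_cohort_spec(n_healthy = 2, n_ad = 2, seed = 7)
  expect_identical(
    generate_subject(spec, "C", 2)$signal,
    generate_subject(spec, "C", 2)$signal
  )
  cohort <- generate_cohort(spec)
  # the cohort member equals the directly generated record, so generation
  # order cannot matter
  idx <- which(vapply(cohort, `[[`, "", "subject_id") == "B02")
  expect_identical(cohort[[idx]]$signal, generate_subject(spec, "B", 2)$signal)
})

test_that("cohorts have the configured group sizes and unique ids", {
  spec <- eeg_cohort_spec(n_healthy = 12, n_ad = 80, n_channels = 1, seed = 3)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 184)
  groups <- vapply(cohort, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("A", "B", "C", "D")]),
               c(12L, 12L, 80L, 80L), ignore_attr = TRUE)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  expect_false(anyDuplicated(ids) > 0)
  small <- generate_cohort(eeg_cohort_spec(n_healthy = 1, n_ad = 1,
                                           n_channels = 1))
  expect_length(small, 4)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(eeg_cohort_spec(duration = 0), "positive")
  expect_error(eeg_cohort_spec(n_healthy = 0), "at least 1")
  expect_error(eeg_cohort_spec(fs = 100, duration = 8.001), "integer")
  expect_error(eeg_cohort_spec(delta_shift = -0.1), "delta_shift")
  spec <- eeg_cohort_spec(n_healthy = 1, n_ad = 1)
  expect_error(generate_subject(spec, "E", 1), "one of")
})

test_that("white noise is reproducible with near-zero mean", {
  x <- white_noise(500, seed = 11)
  expect_length(x, 500)
  expect_lt(abs(mean(x)), 3 / sqrt(500))
  expect_identical(x, white_noise(500, seed = 11))
  expect_length(white_noise(10000, seed = 1), 10000)
  expect_error(white_noise(0), "positive")
})

test_that("delta_shift raises AD delta energy in nearly all channels", {
  spec <- eeg_cohort_spec(
    n_healthy = 40, n_ad = 40, delta_shift = 0.5, seed = 19
  )
  rwe <- function(group) {
    vapply(1:40, function(i) {
      sig <- generate_subject(spec, group, i)$signal
      vapply(seq_len(nrow(sig)), function(ch) {
        relative_wavelet_energy(sig[ch, ], "delta")
      }, 0)
    }, numeric(19))
  }
  mean_a <- rowMeans(rwe("A"))
  mean_c <- rowMeans(rwe("C"))
  expect_gte(mean(mean_c > mean_a), 0.95)
})
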