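test_that("Katz fractal dimension reproduces hand-computed values", {
  expect_equal(katz_fd(c(0, 1, 2, 3)), 1.0, tolerance = 1e-12)
  # D = 4 sqrt(2), d = 4, F = ln 4 / ln(16 / (4 sqrt(2))) = 4/3
  expect_equal(katz_fd(c(0, 1, 0, 1, 0)), 4 / 3, tolerance = 1e-12)
  expect_equal(katz_fd(rep(5, 5)), 1.0, tolerance = 1e-12)
  # any straight line scores exactly 1
  for (slope in c(-2.5, 0.3, 10)) {
    expect_equal(katz_fd(1.7 + slope * (0:99)), 1.0, tolerance = 1e-9)
  }
  expect_error(katz_fd(c(1, 2)), "at least 3")
})

test_that("quadratic entropy hits its closed-form limits", {
  # constant series: every template matches at both lengths, Q = ln(2r)
  expect_equal(quadratic_entropy(rep(1, 50), m = 1, r = 0.5), 0.0,
               tolerance = 1e-12)
  expect_equal(quadratic_entropy(rep(3.3, 40), m = 2, r = 0.2), log(0.4),
               tolerance = 1e-12)
  # exact periodicity: every m-match extends to an (m+1)-match, so E = 0
  expect_equal(quadratic_entropy(c(1, 2, 3, 1, 2, 3, 1, 2), m = 1, r = 0.5),
               0.0, tolerance = 1e-12)
  expect_error(quadratic_entropy(1:10, m = 2, r = 0), "positive")
  expect_error(quadratic_entropy(1:4, m = 2, r = 0.2), "too short")
  # B = 0: undefined, signalled as NA with a warning
  expect_warning(
    out <- quadratic_entropy(c(0, 10, -10, 20, -20, 40, -40, 80), m = 1,
                             r = 1e-6, normalize = FALSE),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("quadratic entropy equals the naive counting oracle", {
  for (n in c(128, 512, 1024)) {
    x <- white_noise(n, seed = n)
    for (m in c(1, 2)) {
      expect_identical(
        quadratic_entropy(x, m = m, r = 0.2),
        oracle_qe(x, m = m, r = 0.2)
      )
    }
  }
})

test_that("the (m, r) grid evaluation matches single-point calls", {
  x <- white_noise(256, seed = 9)
  grid <- eegmarkers:::quadratic_entropy_grid(
    x, m_grid = c(1, 2), r_grid = c(0.1, 0.2, 0.5)
  )
  expect_identical(nrow(grid), 6L)
  for (i in seq_len(nrow(grid))) {
    expect_equal(
      grid$value[i],
      quadratic_entropy(x, m = grid$m[i], r = grid$r[i]),
      tolerance = 1e-12
    )
  }
})

test_that("quadratic entropy is shift invariant and Katz detects lines", {
  x <- white_noise(300, seed = 5)
  expect_equal(
    quadratic_entropy(x + 100, m = 2, r = 0.2),
    quadratic_entropy(x, m = 2, r = 0.2),
    tolerance = 1e-9
  )
})

test_that("relative wavelet energy is a normalised ratio", {
  x <- white_noise(1024, seed = 6)
  expect_equal(relative_wavelet_energy(x, "original"), 1.0, tolerance = 1e-12)
  parts <- vapply(c("beta", "alpha", "theta", "delta"),
                  function(b) relative_wavelet_energy(x, b), 0)
  dec <- dwt_decompose(x, 4)
  d1_frac <- sum(dec$d$d1^2) / (sum(unlist(dec$d)^2) + sum(dec$a^2))
  expect_equal(sum(parts) + d1_frac, 1.0, tolerance = 1e-9)
  # scale invariance of the ratio
  expect_equal(relative_wavelet_energy(3 * x, "delta"),
               relative_wavelet_energy(x, "delta"), tolerance = 1e-12)
  tone6 <- sin(2 * pi * 6 * (0:1023) / 128)
  expect_gte(relative_wavelet_energy(tone6, "theta"), 0.7)
  expect_error(relative_wavelet_energy(rep(0, 1024), "delta"), "zero-energy")
})
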