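test_that("decomposition has dyadic set sizes and conserves energy", {
  x <- white_noise(1024, seed = 1)
  dec <- dwt_decompose(x, levels = 4)
  expect_identical(unname(lengths(dec$d)), c(512L, 256L, 128L, 64L))
  expect_length(dec$a, 64)
  for (seed in 1:20) {
    y <- white_noise(256, seed = seed)
    d <- dwt_decompose(y, levels = 4)
    coef_energy <- sum(unlist(d$d)^2) + sum(d$a^2)
    expect_equal(coef_energy, sum(y^2), tolerance = 1e-9)
    expect_equal(dwt_reconstruct(d), y, tolerance = 1e-9)
  }
  expect_error(dwt_decompose(white_noise(100, 1), levels = 4), "divisible")
})

test_that("one level of the pyramid matches the explicit analysis matrix", {
  n <- 64
  W <- oracle_dwt_matrix(n)
  # the matrix itself is orthogonal
  expect_equal(W %*% t(W), diag(n), tolerance = 1e-12)
  x <- white_noise(n, seed = 2)
  st <- eegmarkers:::dwt_step(x)
  expect_equal(c(st$a, st$d), as.vector(W %*% x), tolerance = 1e-12)
})

test_that("band signals sum back to the original with the 32-64 Hz detail", {
  x <- white_noise(1024, seed = 3)
  bands <- vapply(
    c("beta", "alpha", "theta", "delta"),
    function(b) extract_band(x, b), numeric(1024)
  )
  d1 <- dwt_reconstruct(dwt_decompose(x, 4), keep = "d1")
  expect_equal(rowSums(bands) + d1, x, tolerance = 1e-9)
})

test_that("band extraction is idempotent in coefficient space", {
  x <- white_noise(512, seed = 4)
  for (b in c("beta", "alpha", "theta", "delta")) {
    once <- extract_band(x, b)
    expect_equal(extract_band(once, b), once, tolerance = 1e-6)
  }
  expect_error(extract_band(x, "gamma"), "unknown band")
})

test_that("pure tones land in the mapped dyadic sets", {
  t <- (0:1023) / 128
  frac <- function(x, band) {
    sum(extract_band(x, band)^2) / sum(x^2)
  }
  tone6 <- sin(2 * pi * 6 * t)
  expect_gte(frac(tone6, "theta"), 0.70)
  tone2 <- sin(2 * pi * 2 * t)
  expect_gte(frac(tone2, "delta"), 0.70)
  # 10 Hz sits near the 8 Hz dyadic edge; alpha still dominates, and the
  # extracted fraction agrees with the coefficient-energy ratio exactly
  tone10 <- sin(2 * pi * 10 * t)
  fr <- vapply(c("beta", "alpha", "theta", "delta"),
               function(b) frac(tone10, b), 0)
  expect_identical(names(which.max(fr)), "alpha")
  expect_gte(fr[["alpha"]], 0.6)
  expect_equal(
    fr[["alpha"]], relative_wavelet_energy(tone10, "alpha"),
    tolerance = 1e-9
  )
  # the extracted theta signal keeps most of its energy near 6 Hz; the
  # dyadic subspace projection spreads the rest (spectral oracle)
  expect_gte(
    oracle_band_energy_fraction(extract_band(tone6, "theta"), 128, 3, 9),
    0.7
  )
})
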