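test_that("the CWT is linear and vanishes on the zero series", {
  z <- cwt(rep(0, 128), nv = 2)
  expect_true(all(Mod(z$coefficients) == 0))
  x <- white_noise(128, seed = 1)
  c1 <- cwt(x, nv = 2)
  c2 <- cwt(2 * x, nv = 2)
  expect_equal(c2$coefficients, 2 * c1$coefficients, tolerance = 1e-12)
  expect_error(cwt(x, scales = numeric(0)), "empty scale grid")
})

test_that("a unit impulse reproduces the conjugate wavelet pattern", {
  n <- 128
  x <- rep(0, n)
  t0 <- 40
  x[t0] <- 1
  scale <- 9
  field <- cwt(x, scales = scale)
  b <- seq_len(n)
  u <- (t0 - b) / scale
  expected <- Conj(pi^(-0.25) * exp(1i * 6 * u - u^2 / 2)) / sqrt(scale)
  # the production kernel truncates the Morlet envelope below exp(-18)
  expect_equal(field$coefficients[1, ], expected, tolerance = 1e-6)
})

test_that("the FFT path equals the direct Eq.-style double sum", {
  x <- white_noise(96, seed = 2)
  for (scale in c(3, 11.5)) {
    field <- cwt(x, scales = scale)
    expect_equal(field$coefficients[1, ], oracle_cwt_row(x, scale),
                 tolerance = 1e-7)
  }
})

test_that("self-coherence is total and sign-invariant", {
  x <- white_noise(1024, seed = 3)
  expect_gte(wavelet_coherence(x, x)$summary, 0.99)
  expect_gte(wavelet_coherence(x, -x)$summary, 0.99)
})

test_that("coherence maps stay within [0, 1] and inputs are validated", {
  x <- white_noise(256, seed = 4)
  y <- white_noise(256, seed = 5)
  wc <- wavelet_coherence(x, y, nv = 3)
  expect_true(all(wc$coherence >= 0 & wc$coherence <= 1))
  expect_gte(wc$summary, 0)
  expect_lte(wc$summary, 1)
  expect_error(wavelet_coherence(x, y[1:100]), "equal length")
  expect_error(wavelet_coherence(x, rep(1, 256)), "constant")
})

test_that("independent noise is far less coherent than self-coherence", {
  n_pairs <- 40
  summaries <- vapply(seq_len(n_pairs), function(i) {
    x <- white_noise(1024, seed = 2 * i + 1000)
    y <- white_noise(1024, seed = 2 * i + 1001)
    wavelet_coherence(x, y, nv = 4)$summary
  }, 0)
  self <- wavelet_coherence(
    white_noise(1024, seed = 1), white_noise(1024, seed = 1),
    nv = 4
  )$summary
  expect_gte(self - mean(summaries), 0.2)
})
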