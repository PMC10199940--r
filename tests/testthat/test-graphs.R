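test_that("quantile graphs reproduce hand-constructed transition counts", {
  g <- build_quantile_graph(1:20, q = 20, k = 1)
  super <- cbind(1:19, 2:20)
  expect_true(all(g$adjacency[super] == 1))
  expect_identical(sum(g$adjacency), 19L)

  alt <- rep(c(0, 1), 512)
  g1 <- build_quantile_graph(alt, q = 2, k = 1)
  expect_equal(g1$transition, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_equal(mean_jump_length(g1), 1.0)
  expect_equal(mean_jump_length(build_quantile_graph(alt, q = 2, k = 2)), 0.0)

  expect_equal(mean_jump_length(build_quantile_graph(1:5, q = 5, k = 1)), 0.8)

  # constant series: all mass in one diagonal cell
  gc <- build_quantile_graph(rep(2, 100), q = 4, k = 1)
  expect_identical(sum(gc$adjacency == 99L), 1L)
  expect_identical(sum(gc$adjacency), 99L)
  expect_true(all(gc$adjacency[row(gc$adjacency) != col(gc$adjacency)] == 0))
})

test_that("quantile graph invariants hold on random series", {
  for (seed in 1:10) {
    n <- 50 + 17 * seed
    x <- white_noise(n, seed = seed)
    k <- 1 + (seed %% 5)
    q <- 2 + (seed %% 7)
    g <- build_quantile_graph(x, q = q, k = k)
    expect_identical(sum(g$adjacency), as.integer(n - k))
    rs <- rowSums(g$transition)
    nonzero <- rowSums(g$adjacency) > 0
    expect_equal(rs[nonzero], rep(1, sum(nonzero)), tolerance = 1e-12)
    expect_equal(rs[!nonzero], rep(0, sum(!nonzero)), tolerance = 1e-12)
  }
  expect_error(build_quantile_graph(1:10, q = 2, k = 10), "k")
  expect_error(build_quantile_graph(1:10, q = 1, k = 1), "at least 2")
})

test_that("quantile transition counts match direct enumeration", {
  for (seed in 1:10) {
    x <- white_noise(60, seed = 100 + seed)
    g <- build_quantile_graph(x, q = 5, k = 2)
    expect_identical(g$adjacency, oracle_qg_adjacency(x, 5, 2))
  }
  for (seed in 1:20) {
    n <- sample(20:200, 1)
    x <- round(white_noise(n, seed = 200 + seed), seed %% 2) # induce ties
    q <- sample(2:12, 1)
    k <- sample(seq_len(min(9, n - 1)), 1)
    g <- build_quantile_graph(x, q = q, k = k)
    expect_identical(g$adjacency, oracle_qg_adjacency_fast(x, q, k))
  }
})

test_that("jump lengths are invariant to shifting and scaling the series", {
  x <- white_noise(400, seed = 3)
  base <- mean_jump_length(build_quantile_graph(x, q = 10, k = 3))
  expect_equal(
    mean_jump_length(build_quantile_graph(5 + 2 * x, q = 10, k = 3)),
    base
  )
})

test_that("visibility graphs match the spec example and brute force", {
  g <- build_visibility_graph(c(0.8, 0.2, 0.6, 0.1, 0.9))
  expect_equal(
    g$edges,
    cbind(c(1, 1, 1, 2, 3, 3, 4), c(2, 3, 5, 3, 4, 5, 5)),
    ignore_attr = TRUE
  )
  # convex series: complete graph
  gc <- build_visibility_graph((1:50)^2)
  expect_identical(nrow(gc$edges), as.integer(50 * 49 / 2))

  withr::with_seed(99, {
    for (trial in 1:50) {
      n <- sample(5:200, 1)
      x <- rnorm(n)
      g <- build_visibility_graph(x)
      o <- oracle_visibility_edges(x)
      expect_equal(
        g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE],
        o, ignore_attr = TRUE
      )
      # adjacent points always connected
      expect_true(all(g$adjacency[cbind(1:(n - 1), 2:n)] == 1))
    }
  })
  expect_error(build_visibility_graph(1), "at least 2")
})

test_that("the complexity index vanishes at both eigenvalue extremes", {
  # complete visibility graph (convex series): lambda_max = N - 1, c = 1
  expect_equal(complexity_index(build_visibility_graph((1:50)^2)), 0.0,
               tolerance = 1e-9)
  # path graph: lambda_max = 2 cos(pi / (N + 1)), c = 0
  n <- 50
  path <- Matrix::sparseMatrix(
    i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)), x = 1, dims = c(n, n)
  )
  expect_equal(complexity_index(path), 0.0, tolerance = 1e-7)
  # parabola vertex: c = 1/2 gives the maximum index 1
  cc <- 0.5
  expect_equal(4 * cc * (1 - cc), 1.0)
  expect_error(complexity_index(matrix(0, 2, 2)), "at least 3")
})

test_that("lambda_max respects its graph-theoretic bounds", {
  for (seed in 1:10) {
    x <- white_noise(80, seed = 300 + seed)
    g <- build_visibility_graph(x)
    lam <- eegmarkers:::lambda_max(g$adjacency)
    n <- g$n
    expect_gte(lam, 2 * cos(pi / (n + 1)) - 1e-8)
    expect_lte(lam, n - 1 + 1e-8)
    # cross-check against a dense eigendecomposition
    expect_equal(
      lam,
      max(eigen(as.matrix(g$adjacency), symmetric = TRUE,
                only.values = TRUE)$values),
      tolerance = 1e-7
    )
    idx <- complexity_index(g)
    expect_gte(idx, 0)
    expect_lte(idx, 1)
  }
})

test_that("visibility and jump measures ignore affine transformations", {
  x <- white_noise(150, seed = 8)
  i1 <- complexity_index(build_visibility_graph(x))
  i2 <- complexity_index(build_visibility_graph(10 + 3 * x))
  expect_equal(i1, i2, tolerance = 1e-9)
})
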