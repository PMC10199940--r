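# Time-series-to-network mappings: quantile graphs (directed, weighted) and
# natural visibility graphs (undirected, 0/1), with their scalar summaries.

#' Quantile bin assignment
#'
#' Assigns each point to one of `q` empirical quantile bins through average
#' ranks: `bin = ceiling(q * rank / T)` capped at `q`. Tied values share one
#' average rank and therefore one bin, so constant or heavily tied series stay
#' well defined; for all-distinct values this reproduces left-closed,
#' right-open empirical quantile intervals (top bin closed).
#'
#' @param x Numeric series.
#' @param q Number of quantile bins (at least 2).
#' @return Integer vector of bin indices in `1..q`.
#' @export
quantile_bins <- function(x, q) {
  if (q < 2) stop_eeg("`q` must be at least 2")
  rk <- rank(x, ties.method = "average")
  pmax(1L, pmin(as.integer(q), as.integer(ceiling(q * rk / length(x)))))
}

#' Build a quantile graph from a series
#'
#' Coarse-grains the series into `q` quantiles and counts lag-`k` transitions:
#' entry `(i, j)` of the weighted directed adjacency counts occurrences of
#' quantile `i` at time `t` followed by quantile `j` at `t + k`. The Markov
#' transition matrix is the row-normalised adjacency (rows with no outgoing
#' transitions stay zero).
#'
#' @param x Numeric series.
#' @param q Quantile count; defaults to [default_quantile_count()]
#'   (`2 T^(1/3)` rounded, i.e. 20 at T = 1024).
#' @param k Transition lag, `1 <= k < length(x)`.
#' @return A `quantile_graph`: list with `q`, `k`, `adjacency` (integer
#'   q x q), `transition` (row-stochastic where defined) and `jump_cost`
#'   (`|i - j|` matrix).
#' @export
#' @examples
#' g <- build_quantile_graph(sin(1:200), q = 10, k = 1)
#' mean_jump_length(g)
build_quantile_graph <- function(x, q = default_quantile_count(length(x)),
                                 k = 1) {
  n <- length(x)
  if (k < 1 || k >= n) stop_eeg("`k` must satisfy 1 <= k < length(x)")
  bins <- quantile_bins(x, q)
  q <- as.integer(q)
  from <- bins[seq_len(n - k)]
  to <- bins[seq_len(n - k) + k]
  adjacency <- matrix(
    tabulate((to - 1L) * q + from, nbins = q * q),
    nrow = q, ncol = q
  )
  rs <- rowSums(adjacency)
  transition <- adjacency / ifelse(rs > 0, rs, 1)
  structure(
    list(
      q = q, k = as.integer(k),
      adjacency = adjacency, transition = transition,
      jump_cost = abs(outer(seq_len(q), seq_len(q), "-"))
    ),
    class = "quantile_graph"
  )
}

#' @export
print.quantile_graph <- function(x, ...) {
  cat(
    "<quantile_graph> Q =", x$q, " k =", x$k, ";",
    sum(x$adjacency), "transitions\n"
  )
  invisible(x)
}

#' Mean jump length of a quantile graph
#'
#' `Delta_k = (1/Q) * sum_ij W_k[i, j] * |i - j|`: the average quantile
#' distance travelled per lag-`k` transition, accumulated over rows of the
#' Markov transition matrix. Large values flag erratic series whose
#' transitions jump across many quantiles.
#'
#' @param graph A [build_quantile_graph()] result.
#' @return Scalar mean jump length.
#' @export
mean_jump_length <- function(graph) {
  stopifnot(inherits(graph, "quantile_graph"))
  sum(graph$transition * graph$jump_cost) / graph$q
}

#' Build a natural visibility graph
#'
#' Connects time points `i < j` when every intermediate point lies strictly
#' below the straight chord between `(i, x[i])` and `(j, x[j])`; adjacent
#' points are always connected, so the path graph on the time axis is always a
#' subgraph.
#'
#' @param x Numeric series of length at least 2.
#' @return A `visibility_graph`: list with `n`, `edges` (two-column matrix of
#'   node pairs, `from < to`) and `adjacency` (sparse symmetric 0/1 Matrix).
#' @export
#' @examples
#' g <- build_visibility_graph(c(0.8, 0.2, 0.6, 0.1, 0.9))
#' g$edges
build_visibility_graph <- function(x) {
  n <- length(x)
  if (n < 2) stop_eeg("visibility graph needs at least 2 points")
  edges <- visibility_edges_cpp(as.numeric(x))
  adjacency <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]),
    j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n, n)
  )
  structure(
    list(n = n, edges = edges, adjacency = adjacency),
    class = "visibility_graph"
  )
}

#' @export
print.visibility_graph <- function(x, ...) {
  cat("<visibility_graph>", x$n, "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# Largest eigenvalue of a symmetric nonnegative adjacency by shifted power
# iteration (A + I keeps the top eigenvalue strictly dominant even for
# bipartite graphs). Deterministic uniform start vector; falls back to a dense
# eigendecomposition for small matrices if the iteration is slow to converge.
lambda_max <- function(adjacency, tol = 1e-10, max_iter = 20000L) {
  n <- nrow(adjacency)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(adjacency %*% v) + v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    w <- w / nw
    lam_new <- sum(w * (as.numeric(adjacency %*% w) + w))
    if (abs(lam_new - lam) < tol * max(1, abs(lam_new))) {
      return(lam_new - 1)
    }
    lam <- lam_new
    v <- w
  }
  if (n <= 4096) {
    ev <- eigen(as.matrix(adjacency), symmetric = TRUE, only.values = TRUE)
    return(max(ev$values))
  }
  lam - 1
}

#' Visibility-graph complexity index
#'
#' Normalises the largest adjacency eigenvalue between its extremes -- the
#' path graph (`2 cos(pi / (N + 1))`, the minimum given that adjacent points
#' are always connected) and the complete graph (`N - 1`) -- to
#' `c in [0, 1]`, and returns `I = 4 c (1 - c)`. Both extremes score 0; the
#' index peaks at 1 midway, flagging series that are neither trivially smooth
#' nor fully convex.
#'
#' @param graph A [build_visibility_graph()] result, or a symmetric 0/1
#'   adjacency matrix with at least 3 nodes.
#' @return Complexity index in `[0, 1]`.
#' @export
#' @examples
#' complexity_index(build_visibility_graph((1:50)^2)) # complete graph -> 0
complexity_index <- function(graph) {
  adjacency <- if (inherits(graph, "visibility_graph")) {
    graph$adjacency
  } else {
    graph
  }
  n <- nrow(adjacency)
  if (is.null(n) || n < 3) stop_eeg("complexity index needs at least 3 nodes")
  lam <- lambda_max(adjacency)
  lo <- 2 * cos(pi / (n + 1))
  cc <- (lam - lo) / (n - 1 - lo)
  cc <- min(1, max(0, cc))
  4 * cc * (1 - cc)
}
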