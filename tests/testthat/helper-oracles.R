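# Independent brute-force oracles used across the descriptor tests.
# These deliberately avoid the implementation's code paths (matrix powers,
# hand-rolled DFS with weight accumulation): walks are enumerated one step at
# a time, and simple paths come from igraph's path enumerator.

# Number of closed walks of length k, by explicit enumeration.
oracle_srw <- function(g, k) {
  A <- adjacency_matrix(g)
  nbrs <- lapply(seq_len(nrow(A)), function(v) which(A[v, ] > 0))
  total <- 0L
  rec <- function(v, start, left) {
    if (left == 0L) {
      if (v == start) total <<- total + 1L
      return(invisible())
    }
    for (u in nbrs[[v]]) rec(u, start, left - 1L)
  }
  for (s in seq_len(nrow(A))) rec(s, s, k)
  total
}

# Bond-order weighted simple-path count via igraph::all_simple_paths.
oracle_pipc <- function(g, k) {
  W <- adjacency_matrix(g) * 0
  b <- g$bonds
  if (nrow(b)) {
    W[cbind(b$i, b$j)] <- b$order
    W[cbind(b$j, b$i)] <- b$order
  }
  ig <- igraph::graph_from_adjacency_matrix(adjacency_matrix(g),
                                            mode = "undirected")
  total <- 0
  for (v in seq_len(nrow(W))) {
    paths <- igraph::all_simple_paths(ig, from = v, cutoff = k)
    for (p in paths) {
      p <- as.integer(p)
      if (length(p) == k + 1L)
        total <- total + prod(W[cbind(p[-length(p)], p[-1L])])
    }
  }
  total / 2
}

# Build a molgraph directly from an edge list of all-carbon single bonds.
carbon_graph <- function(edges) {
  molecular_graph(rep("C", max(edges)), cbind(edges, 1L))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %g of %.6g", object, tol, expected))
}
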