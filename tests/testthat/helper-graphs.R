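# Shared fixtures and independent oracles, built in code.

# build a cell_graph from an edge matrix/list using the public API
build_graph <- function(n, edges) {
  g <- make_empty_graph(n)
  if (length(edges)) {
    if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
    for (k in seq_len(nrow(edges))) {
      res <- try_add_edge(g, edges[k, 1L], edges[k, 2L])
      stopifnot(res$outcome == "added")
      g <- res$graph
    }
  }
  g
}

path_graph <- function(n) build_graph(n, cbind(seq_len(n - 1L), 2:n))

cycle_graph <- function(n) {
  stopifnot(n >= 3L)
  build_graph(n, rbind(cbind(seq_len(n - 1L), 2:n), c(1L, n)))
}

# independent component oracle: boolean transitive closure of the adjacency
# matrix (repeated squaring), components read off the closure rows
oracle_components <- function(n, edges) {
  A <- diag(TRUE, n)
  if (length(edges)) {
    edges <- matrix(edges, ncol = 2L, byrow = FALSE)
    if (ncol(edges) != 2L) edges <- t(edges)
    A[edges] <- TRUE
    A[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  memb <- apply(A, 1L, function(row) which(row)[1L])
  sort(as.integer(table(memb)), decreasing = TRUE)
}

# all degree-capped edge subsets on n labelled vertices (n small)
all_capped_subsets <- function(n) {
  pairs <- t(utils::combn(n, 2L))
  np <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^np - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(np) - 1L)) != 0L)
    deg <- tabulate(pairs[sel, , drop = FALSE], nbins = n)
    if (all(deg <= 2L)) out[[length(out) + 1L]] <- pairs[sel, , drop = FALSE]
  }
  out
}
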