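#' Degree-capped cell graphs
#'
#' A `cell_graph` represents the interaction state of a population of cells:
#' a fixed set of `n` vertices (cells) with an undirected, loop-free edge set
#' in which every vertex has degree at most 2. Under this cap every connected
#' component is a simple path (a raft-like chain of cells) or a simple cycle.
#'
#' The object is a plain list with fields
#' \describe{
#'   \item{n}{number of cells.}
#'   \item{edges}{integer matrix with two columns, one row per undirected
#'     edge, stored canonically with `edges[, 1] < edges[, 2]`.}
#'   \item{degree}{integer vector of per-vertex degrees, each in \{0, 1, 2\}.}
#' }
#'
#' @param n positive integer, the number of cells.
#' @return A `cell_graph` with `n` vertices and no edges.
#' @examples
#' g <- make_empty_graph(4)
#' average_degree(g)
#' @export
make_empty_graph <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  structure(
    list(
      n = n,
      edges = matrix(integer(0), ncol = 2L,
                     dimnames = list(NULL, c("i", "j"))),
      degree = integer(n)
    ),
    class = "cell_graph"
  )
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d edges, average degree %.4g\n",
              x$n, nrow(x$edges), average_degree(x)))
  invisible(x)
}

.check_vertex_ids <- function(g, i, j) {
  ids <- c(i, j)
  if (any(!is.finite(ids)) || any(ids < 1) || any(ids > g$n) ||
      any(ids != as.integer(ids))) {
    stop(sprintf("vertex ids must be integers in [1, %d]", g$n), call. = FALSE)
  }
}

.has_edge <- function(g, a, b) {
  ne <- nrow(g$edges)
  ne > 0L && any(g$edges[, 1L] == a & g$edges[, 2L] == b)
}

#' Attempt to add one edge under the raft rules
#'
#' Applies the single-edge update rule shared by all three processes: an edge
#' between cells `i` and `j` is created only if `i != j`, the edge is not
#' already present, and neither endpoint already touches two cells (the
#' degree cap). Otherwise the graph is unchanged and the specific rejection
#' reason is reported.
#'
#' @param g a [cell_graph][make_empty_graph].
#' @param i,j vertex ids in `1:g$n`.
#' @return A list with components `graph` (the possibly updated `cell_graph`)
#'   and `outcome`, one of `"added"`, `"rejected_self"`, `"rejected_exists"`,
#'   `"rejected_degree"`.
#' @examples
#' g <- make_empty_graph(4)
#' res <- try_add_edge(g, 1, 2)
#' res$outcome
#' @export
try_add_edge <- function(g, i, j) {
  stopifnot(inherits(g, "cell_graph"))
  .check_vertex_ids(g, i, j)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) {
    return(list(graph = g, outcome = "rejected_self"))
  }
  a <- min(i, j); b <- max(i, j)
  if (.has_edge(g, a, b)) {
    return(list(graph = g, outcome = "rejected_exists"))
  }
  if (g$degree[a] >= 2L || g$degree[b] >= 2L) {
    return(list(graph = g, outcome = "rejected_degree"))
  }
  g$edges <- rbind(g$edges, c(a, b))
  g$degree[a] <- g$degree[a] + 1L
  g$degree[b] <- g$degree[b] + 1L
  list(graph = g, outcome = "added")
}

#' Average degree of a cell graph
#'
#' Each undirected contact is counted once and contributes degree to both of
#' its endpoints, so the average degree is `2 * n_edges / n`; under the degree
#' cap it lies in `[0, 2]`.
#'
#' @param g a [cell_graph][make_empty_graph].
#' @return A number in `[0, 2]`.
#' @export
average_degree <- function(g) {
  stopifnot(inherits(g, "cell_graph"))
  2 * nrow(g$edges) / g$n
}

#' Connected components of a cell graph
#'
#' Decomposes the graph into maximal connected sets of cells. Because of the
#' degree cap each component is either a simple path (an open chain of cells)
#' or a simple cycle, which the function verifies and reports.
#'
#' @param g a [cell_graph][make_empty_graph].
#' @return A `component_decomposition`: list with `components` (list of
#'   integer vertex vectors), `sizes` (integer vector), `giant_size`
#'   (largest component size; 1 on an edgeless graph) and `is_cycle`
#'   (logical, per component).
#' @examples
#' g <- make_empty_graph(5)
#' g <- try_add_edge(g, 1, 2)$graph
#' g <- try_add_edge(g, 2, 3)$graph
#' connected_components(g)$sizes
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "cell_graph"))
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges) > 0L) {
    ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  }
  comp <- igraph::components(ig)
  components <- split(seq_len(g$n), comp$membership)
  names(components) <- NULL
  sizes <- as.integer(comp$csize)
  # edges within each component; degree cap => size-1 (path) or size (cycle)
  if (nrow(g$edges) > 0L) {
    ecomp <- comp$membership[g$edges[, 1L]]
    ecount <- tabulate(ecomp, nbins = comp$no)
  } else {
    ecount <- integer(comp$no)
  }
  if (!all(ecount == sizes - 1L | ecount == sizes)) {
    stop("internal error: component neither path nor cycle (degree cap violated?)")
  }
  structure(
    list(
      components = components,
      sizes = sizes,
      giant_size = max(sizes),
      is_cycle = ecount == sizes
    ),
    class = "component_decomposition"
  )
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d components, giant size %d (%d cycle(s))\n",
              length(x$sizes), x$giant_size, sum(x$is_cycle)))
  invisible(x)
}

#' Write / read a cell graph as a plain-text edge list
#'
#' Two tab-separated columns of 1-based vertex ids, one undirected edge per
#' line with `i < j`, preceded by a `#`-prefixed header line carrying the
#' number of vertices, e.g. `# n_vertices=1000`.
#'
#' @param g a [cell_graph][make_empty_graph].
#' @param path file path.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist` returns
#'   a `cell_graph`.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "cell_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_vertices=%d", g$n), con)
  if (nrow(g$edges) > 0L) {
    writeLines(paste(g$edges[, 1L], g$edges[, 2L], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^#\\s*n_vertices=\\d+\\s*$", lines[1L])) {
    stop("edge-list file must start with a '# n_vertices=<N>' header", call. = FALSE)
  }
  n <- as.integer(sub("^#\\s*n_vertices=(\\d+)\\s*$", "\\1", lines[1L]))
  g <- make_empty_graph(n)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    ij <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    if (length(ij) != 2L) stop("malformed edge line: ", ln, call. = FALSE)
    res <- try_add_edge(g, ij[1L], ij[2L])
    if (res$outcome != "added") {
      stop("invalid edge list (", res$outcome, "): ", ln, call. = FALSE)
    }
    g <- res$graph
  }
  g
}
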