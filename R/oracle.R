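#' Exact Markov-chain reference for Model 1 on small populations
#'
#' For populations of up to 5 cells the Model 1 graph process can be solved
#' exactly: every labelled degree-capped graph is a Markov state, and the
#' uniform ordered draw `(i, j)` from `{1..n}^2` induces a row-stochastic
#' transition matrix with entries that are integer multiples of `1/n^2`.
#' These functions enumerate the state space, build the exact kernel, and
#' compute exact hitting statistics of the threshold-component property,
#' serving as ground truth for the stochastic simulator.
#'
#' @param n number of cells, at most 5 (the labelled state space grows
#'   combinatorially).
#' @name model1_oracle
NULL

.oracle_pairs <- function(n) {
  if (n < 2L) matrix(integer(0), nrow = 2L) else utils::combn(n, 2L)
}

.mask_degrees <- function(mask, pairs, n) {
  sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ncol(pairs)) - 1L)) != 0L)
  tabulate(pairs[, sel, drop = FALSE], nbins = n)
}

.mask_to_graph <- function(mask, pairs, n) {
  sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ncol(pairs)) - 1L)) != 0L)
  e <- t(pairs[, sel, drop = FALSE])
  structure(
    list(n = n,
         edges = matrix(as.integer(e), ncol = 2L,
                        dimnames = list(NULL, c("i", "j"))),
         degree = .mask_degrees(mask, pairs, n)),
    class = "cell_graph"
  )
}

.graph_mask <- function(g, pairs) {
  if (nrow(g$edges) == 0L) return(0L)
  key <- (g$edges[, 1L] - 1L) * (max(pairs) + 1L) + g$edges[, 2L]
  pkey <- (pairs[1L, ] - 1L) * (max(pairs) + 1L) + pairs[2L, ]
  pos <- match(key, pkey)
  if (anyNA(pos)) stop("edge not found in pair enumeration", call. = FALSE)
  sum(bitwShiftL(1L, pos - 1L))
}

#' @rdname model1_oracle
#' @return `enumerate_states`: the complete, duplicate-free list of labelled
#'   graphs on `n` vertices with maximum degree 2, as `cell_graph` objects.
#'   Attributes `masks` (edge-subset bitmask per state, in the pair order of
#'   `utils::combn(n, 2)`), `pairs` and `n` identify each state.
#' @examples
#' length(enumerate_states(3))  # all 8 edge subsets respect the cap on 3 cells
#' @export
enumerate_states <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (n > 5L) {
    stop("exact enumeration is supported for n <= 5 only; use run_process() ",
         "with many replicates for larger populations", call. = FALSE)
  }
  n <- as.integer(n)
  pairs <- .oracle_pairs(n)
  np <- ncol(pairs)
  masks <- 0:(2^np - 1)
  keep <- vapply(masks, function(mk) {
    max(c(0L, .mask_degrees(mk, pairs, n))) <= .DEGREE_CAP
  }, logical(1))
  masks <- as.integer(masks[keep])
  states <- lapply(masks, .mask_to_graph, pairs = pairs, n = n)
  attr(states, "masks") <- masks
  attr(states, "pairs") <- pairs
  attr(states, "n") <- n
  states
}

#' @rdname model1_oracle
#' @param states the result of [enumerate_states()].
#' @return `exact_transition_matrix`: the row-stochastic kernel; entry
#'   `(s, s')` is the number of ordered draws `(i, j)` transforming `s` into
#'   `s'` under the Model 1 rules, divided by `n^2`. Self-transitions
#'   collect all no-op draws (`i == j`, existing edge, degree cap).
#' @export
exact_transition_matrix <- function(states) {
  masks <- attr(states, "masks")
  pairs <- attr(states, "pairs")
  n <- attr(states, "n")
  if (is.null(masks) || is.null(n)) {
    stop("`states` must come from enumerate_states()", call. = FALSE)
  }
  ns <- length(masks)
  P <- matrix(0, ns, ns, dimnames = list(masks, masks))
  np <- ncol(pairs)
  for (s in seq_len(ns)) {
    deg <- states[[s]]$degree
    mask <- masks[s]
    self <- n  # the i == j draws
    for (p in seq_len(np)) {
      bit <- bitwShiftL(1L, p - 1L)
      i <- pairs[1L, p]; j <- pairs[2L, p]
      if (bitwAnd(mask, bit) != 0L ||
          deg[i] >= .DEGREE_CAP || deg[j] >= .DEGREE_CAP) {
        self <- self + 2L   # ordered draws (i,j) and (j,i) are no-ops
      } else {
        dest <- match(bitwOr(mask, bit), masks)
        P[s, dest] <- P[s, dest] + 2 / n^2
      }
    }
    P[s, s] <- P[s, s] + self / n^2
  }
  P
}

#' @rdname model1_oracle
#' @return `exact_chain`: convenience bundle of states, masks, per-state
#'   giant-component sizes and the transition matrix, as an `exact_chain`.
#' @export
exact_chain <- function(n) {
  states <- enumerate_states(n)
  giant <- vapply(states, function(g) connected_components(g)$giant_size,
                  integer(1))
  structure(
    list(n = attr(states, "n"),
         states = states,
         masks = attr(states, "masks"),
         pairs = attr(states, "pairs"),
         giant = giant,
         transition = exact_transition_matrix(states)),
    class = "exact_chain"
  )
}

#' @export
print.exact_chain <- function(x, ...) {
  cat(sprintf("<exact_chain> Model 1 on %d labelled cells: %d states\n",
              x$n, length(x$masks)))
  invisible(x)
}

#' Map a small graph to its index in an exact chain
#'
#' @param chain an [exact_chain()].
#' @param g a `cell_graph` on the same vertex set.
#' @return The state index of `g` within `chain$states`.
#' @export
state_index <- function(chain, g) {
  stopifnot(inherits(chain, "exact_chain"), inherits(g, "cell_graph"),
            g$n == chain$n)
  match(.graph_mask(g, chain$pairs), chain$masks)
}

#' Exact hitting statistics of the threshold-component property
#'
#' Treats the states whose giant component has at least `m` cells as
#' absorbing (the property is monotone under Model 1, so they are closed),
#' solves the standard absorbing-chain linear system for the expected
#' hitting time from the empty graph, and computes the exact distribution
#' `P(tau = t)` by forward iteration up to `horizon`.
#'
#' @param chain an [exact_chain()].
#' @param m threshold component size, `1 <= m <= n`.
#' @param horizon largest time for the hitting distribution.
#' @return An `exact_hitting_stats` list: `expected_tau`, `pmf` (data frame
#'   with `t`, `prob` for `t = 0..horizon`), `mass` (total pmf mass within
#'   the horizon) and `residual` (linear-solve residual, for auditing).
#' @examples
#' ch <- exact_chain(2)
#' exact_hitting_stats(ch, m = 2)$expected_tau  # geometric with success 1/2
#' @export
exact_hitting_stats <- function(chain, m, horizon = 500L) {
  stopifnot(inherits(chain, "exact_chain"))
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != as.integer(m)) {
    stop("`m` must be a single positive integer", call. = FALSE)
  }
  if (m > chain$n) {
    stop(sprintf("threshold m = %d exceeds the population size n = %d: the property is unreachable",
                 m, chain$n), call. = FALSE)
  }
  absorbing <- chain$giant >= m
  start <- match(0L, chain$masks)
  P <- chain$transition
  if (absorbing[start]) {
    pmf <- data.frame(t = 0:horizon, prob = c(1, rep(0, horizon)))
    return(structure(list(expected_tau = 0, pmf = pmf, mass = 1, residual = 0),
                     class = "exact_hitting_stats"))
  }
  tr <- which(!absorbing)
  Q <- P[tr, tr, drop = FALSE]
  A <- diag(length(tr)) - Q
  h <- solve(A, rep(1, length(tr)))
  residual <- max(abs(A %*% h - 1))
  expected <- unname(h[match(start, tr)])
  # forward iteration for the hitting distribution
  p <- numeric(length(chain$masks))
  p[start] <- 1
  prob <- numeric(horizon + 1L)
  prob[1L] <- 0
  absorbed_prev <- 0
  for (t in seq_len(horizon)) {
    p <- as.vector(p %*% P)
    absorbed <- sum(p[absorbing])
    prob[t + 1L] <- absorbed - absorbed_prev
    absorbed_prev <- absorbed
  }
  structure(
    list(expected_tau = expected,
         pmf = data.frame(t = 0:horizon, prob = prob),
         mass = absorbed_prev,
         residual = residual),
    class = "exact_hitting_stats"
  )
}

#' @export
print.exact_hitting_stats <- function(x, ...) {
  cat(sprintf("<exact_hitting_stats> E[tau] = %.6g (pmf mass %.6g within horizon)\n",
              x$expected_tau, x$mass))
  invisible(x)
}
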