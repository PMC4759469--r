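#' Closed-form hitting-time theory for raft formation
#'
#' Within a dense clump of `n` cells in which any pair may interact, edges
#' appear with per-pair probability `c/n` for an edge-intensity parameter
#' `c`. A threshold raft of `m` cells is reachable only when
#' `m >= (1 - exp(-c)) * n`; the minimal physically realistic intensity is
#' therefore `c_min = |log(1 - m/n)|`, and with `q = c_min/n` the
#' (unnormalized) probability of first assembling the threshold chain at
#' discrete time `t` is `t * q * (1-q)^(t-1)`. These functions implement the
#' threshold relation, the minimal intensity, the hitting curve, its
#' continuous-time derivative, the mode, and the normalized cumulative form.
#'
#' @param m positive integer threshold (cells in the raft), `1 <= m < n`
#'   (equality `m == n` is allowed only by `threshold_ok`).
#' @param n positive integer clump size.
#' @param c nonnegative edge-intensity parameter.
#' @param t time, in discrete steps for the pdf/cdf and as a continuous
#'   variable for the derivative and mode; vectorized.
#' @name raft_theory
NULL

.check_mn <- function(m, n, strict = TRUE) {
  if (length(m) != 1L || length(n) != 1L || !is.finite(m) || !is.finite(n) ||
      m < 1 || n < 1 || m != as.integer(m) || n != as.integer(n)) {
    stop("`m` and `n` must be single positive integers", call. = FALSE)
  }
  if (strict && m >= n) {
    stop("`m` must be strictly less than `n` (log(1 - m/n) diverges at m = n)",
         call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname raft_theory
#' @return `threshold_ok`: `TRUE` iff `m >= (1 - exp(-c)) * n`, i.e. the
#'   threshold is compatible with intensity `c`.
#' @examples
#' threshold_ok(6, 10, 0.5)
#' c_min(6, 10)
#' t_mode(6, 10)
#' @export
threshold_ok <- function(m, n, c) {
  .check_mn(m, n, strict = FALSE)
  stopifnot(length(c) == 1L, is.finite(c), c >= 0)
  m >= (1 - exp(-c)) * n
}

#' @rdname raft_theory
#' @return `c_min`: the minimal intensity `|log(1 - m/n)|`; depends on `m`
#'   and `n` only through the ratio `m/n`.
#' @export
c_min <- function(m, n) {
  .check_mn(m, n)
  abs(log(1 - m / n))
}

.q_min <- function(m, n) {
  q <- c_min(m, n) / n
  if (q >= 1) {
    stop("per-step success probability c_min/n >= 1: the threshold is not ",
         "physically realizable at this clump size (realizability requires ",
         "c >= |log(1 - m/n)| with c/n < 1)", call. = FALSE)
  }
  q
}

#' @rdname raft_theory
#' @return `hitting_pdf`: the unnormalized hitting curve
#'   `t * q * (1-q)^(t-1)` with `q = c_min(m, n)/n` (a proportional lower
#'   bound, not a normalized density). `hitting_pdf_general`: the same with
#'   `q = c/n` for any admissible `c >= c_min`.
#' @export
hitting_pdf <- function(t, m, n) {
  q <- .q_min(m, n)
  stopifnot(all(is.finite(t)), all(t >= 0))
  t * q * (1 - q)^(t - 1)
}

#' @rdname raft_theory
#' @export
hitting_pdf_general <- function(t, m, n, c) {
  cmin <- c_min(m, n)
  stopifnot(length(c) == 1L, is.finite(c))
  if (c < cmin - 1e-12) {
    stop(sprintf("`c` must be at least c_min(m, n) = %.6g for the threshold to be realizable", cmin),
         call. = FALSE)
  }
  q <- c / n
  if (q >= 1) stop("`c/n` must be < 1", call. = FALSE)
  stopifnot(all(is.finite(t)), all(t >= 0))
  t * q * (1 - q)^(t - 1)
}

#' @rdname raft_theory
#' @param normalized divide by the closed-form total mass
#'   `sum_{t>=1} t q (1-q)^(t-1) = 1/q`, so the cdf tends to 1; set `FALSE`
#'   for the raw cumulative sum.
#' @return `hitting_cdf`: cumulative sum of the hitting curve over integer
#'   steps `1..floor(t)`, normalized by default.
#' @export
hitting_cdf <- function(t, m, n, normalized = TRUE) {
  q <- .q_min(m, n)
  stopifnot(all(is.finite(t)), all(t >= 0))
  tmax <- max(floor(t), 1)
  steps <- seq_len(tmax)
  csum <- c(0, cumsum(steps * q * (1 - q)^(steps - 1)))
  out <- csum[pmax(floor(t), 0) + 1]
  if (normalized) out * q else out
}

#' @rdname raft_theory
#' @return `hitting_pdf_derivative`: the derivative of the hitting curve in
#'   continuous `t`, `q (1-q)^(t-1) (1 + t log(1-q))`.
#' @export
hitting_pdf_derivative <- function(t, m, n) {
  q <- .q_min(m, n)
  stopifnot(all(is.finite(t)), all(t > 0))
  q * (1 - q)^(t - 1) * (1 + t * log(1 - q))
}

#' @rdname raft_theory
#' @return `t_mode`: the continuous argmax of the hitting curve,
#'   `-1 / log(1 - c_min(m, n)/n)`. Grows without bound as `n` increases at
#'   fixed ratio `m/n`.
#' @export
t_mode <- function(m, n) {
  q <- .q_min(m, n)
  -1 / log(1 - q)
}
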