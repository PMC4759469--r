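#' Gamma matching of the hitting-time law
#'
#' The hitting curve `t C (1-C)^(t-1)` with `C = |log(1 - m/n)|/n` has the
#' general shape of a gamma density, which suggests relating gamma
#' parameters `(A, k, theta)` fitted to empirical hitting times back to the
#' density threshold `m`. Matching the first-order (linear-in-`t`) terms of
#' the scaled gamma density against the hitting curve gives
#' `C = t^k / (2 A Gamma(k) theta^(k+2) + t^k)`, and with the small-shape
#' approximation `t^k ~ 1` the recovered threshold
#' `m = n (1 - exp(-n C))` is approximately independent of `t`. The
#' factorial `(k-1)!` is realized as `Gamma(k)` so non-integer shapes are
#' admitted.
#'
#' @param m,n threshold and clump size, `1 <= m < n`.
#' @param A proportionality constant of the scaled gamma density (may be
#'   negative, in which case a warning is raised and `A` is treated purely
#'   as a scale constant, not a density normalizer).
#' @param k gamma shape (> 0). The small-`k` regime (`k <= 0.1`) is where
#'   the recovered threshold is time-independent; larger `k` triggers a
#'   warning in [threshold_from_gamma()].
#' @param theta gamma scale (> 0).
#' @param t evaluation time for the first-order matching; `NULL` (default)
#'   applies the small-`k` approximation `t^k ~ 1`.
#' @name gamma_link
NULL

.check_gamma_params <- function(k, theta) {
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop("`theta` must be a single positive number", call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname gamma_link
#' @return `C_from_threshold`: the compound constant
#'   `C = |log(1 - m/n)|/n`, identical to `c_min(m, n)/n` and to the
#'   per-step success probability `q` of [hitting_pdf()].
#' @examples
#' C_from_threshold(6, 10)
#' @export
C_from_threshold <- function(m, n) {
  .q_min(m, n)
}

#' @rdname gamma_link
#' @return `gamma_pdf_scaled`: `A t^(k-1) exp(-t/theta) / (theta^k Gamma(k))`;
#'   with `A = 1` this is the standard gamma density and integrates to 1.
#' @export
gamma_pdf_scaled <- function(t, A, k, theta) {
  .check_gamma_params(k, theta)
  stopifnot(length(A) == 1L, is.finite(A))
  stopifnot(all(is.finite(t)), all(t >= 0))
  A * stats::dgamma(t, shape = k, scale = theta)
}

#' @rdname gamma_link
#' @return `match_first_order`: the estimate
#'   `C = t^k / (2 A Gamma(k) theta^(k+2) + t^k)` obtained by matching
#'   first-order terms (with `t^k = 1` when `t` is `NULL`).
#' @export
match_first_order <- function(A, k, theta, t = NULL) {
  .check_gamma_params(k, theta)
  stopifnot(length(A) == 1L, is.finite(A))
  if (A < 0) {
    warning("negative `A`: treated purely as a scale constant; the recovered C may leave (0, 1)")
  }
  tk <- if (is.null(t)) 1 else {
    stopifnot(length(t) == 1L, is.finite(t), t > 0)
    t^k
  }
  denom <- 2 * A * gamma(k) * theta^(k + 2) + tk
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    stop("degenerate gamma parameters: vanishing denominator in first-order matching",
         call. = FALSE)
  }
  tk / denom
}

#' @rdname gamma_link
#' @return `threshold_from_gamma`: the threshold estimate
#'   `m = n (1 - exp(-n C))` (a real number; round if an integer cell count
#'   is wanted), inverting the matching relation.
#' @examples
#' A <- solve_A(60, 100, k = 0.01, theta = 2)
#' threshold_from_gamma(A, k = 0.01, theta = 2, n = 100)
#' @export
threshold_from_gamma <- function(A, k, theta, n, t = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (k > 0.1) {
    warning("`k` > 0.1: outside the small-shape regime, the recovered threshold depends on `t`")
  }
  C <- match_first_order(A, k, theta, t = t)
  if (!is.finite(C) || C <= 0 || C >= 1) {
    stop(sprintf("recovered C = %.6g lies outside (0, 1): gamma parameters are inconsistent with a realizable threshold", C),
         call. = FALSE)
  }
  n * (1 - exp(-n * C))
}

#' @rdname gamma_link
#' @return `solve_A`: the scale constant consistent with threshold `(m, n)`,
#'   `A = (1/C - 1) / (2 Gamma(k) theta^(k+2))` with
#'   `C = C_from_threshold(m, n)`.
#' @export
solve_A <- function(m, n, k, theta) {
  .check_gamma_params(k, theta)
  C <- C_from_threshold(m, n)
  (1 / C - 1) / (2 * gamma(k) * theta^(k + 2))
}

#' Fit a gamma distribution to hitting-time samples
#'
#' Maximum-likelihood gamma shape/scale on uncensored hitting-time samples,
#' a least-squares scale constant `A` matching the empirical histogram
#' density against [gamma_pdf_scaled()], and a Kolmogorov-Smirnov statistic
#' against the fitted distribution.
#'
#' @param samples numeric vector of positive, uncensored hitting times
#'   (`NA`s, treated as censored, are dropped with a message recording the
#'   censoring fraction); at least 20 uncensored values are required.
#' @return A `raft_gamma_fit`: list with `k`, `theta`, `A`, `ks_statistic`,
#'   `loglik`, `n_used` and `censoring_fraction`.
#' @examples
#' set.seed(1)
#' fit_gamma(rgamma(200, shape = 3, scale = 2))
#' @export
fit_gamma <- function(samples) {
  if (!is.numeric(samples) || !length(samples)) {
    stop("`samples` must be a numeric vector", call. = FALSE)
  }
  n_total <- length(samples)
  x <- samples[is.finite(samples)]
  cens_frac <- 1 - length(x) / n_total
  if (cens_frac > 0) {
    message(sprintf("dropping %.1f%% censored/non-finite samples before fitting",
                    100 * cens_frac))
  }
  if (length(x) < 20L) {
    stop("need at least 20 uncensored samples to fit", call. = FALSE)
  }
  if (any(x <= 0)) stop("hitting times must be positive", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("all samples are equal: gamma fit is degenerate", call. = FALSE)
  }
  # fitdistr probes infeasible parameter values during optimization; the
  # resulting NaN warnings are part of its normal operation
  fit <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  k <- unname(fit$estimate["shape"])
  theta <- 1 / unname(fit$estimate["rate"])
  # least-squares scale match of the empirical histogram density
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  gd <- stats::dgamma(h$mids, shape = k, scale = theta)
  A <- if (sum(gd^2) > 0) sum(h$density * gd) / sum(gd^2) else NA_real_
  ks <- suppressWarnings(
    stats::ks.test(x, "pgamma", shape = k, scale = theta)$statistic
  )
  structure(
    list(k = k, theta = theta, A = A,
         ks_statistic = unname(ks),
         loglik = fit$loglik,
         n_used = length(x),
         censoring_fraction = cens_frac),
    class = "raft_gamma_fit"
  )
}

#' @export
print.raft_gamma_fit <- function(x, ...) {
  cat(sprintf("<raft_gamma_fit> k (shape) = %.4g, theta (scale) = %.4g, A = %.4g\n",
              x$k, x$theta, x$A))
  cat(sprintf("  n = %d (censoring fraction %.3f), KS statistic = %.4g\n",
              x$n_used, x$censoring_fraction, x$ks_statistic))
  invisible(x)
}
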