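test_that("C_from_threshold is the per-step success probability of the hitting law", {
  expect_equal(C_from_threshold(6, 10), abs(log(0.4)) / 10, tolerance = 1e-12)
  expect_equal(C_from_threshold(6, 10), 0.09163, tolerance = 1e-4)
  expect_lt(C_from_threshold(1, 1000), 1.1e-6)
  # exactly the q used by the hitting curve: pdf at t = 1 is q
  expect_identical(C_from_threshold(6, 10), hitting_pdf(1, 6, 10))
  expect_error(C_from_threshold(10, 10), "strictly less")
})

test_that("scaled gamma density has unit mass at A = 1 and the documented shape", {
  mass <- stats::integrate(function(t) gamma_pdf_scaled(t, 1, 3, 2),
                           0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  # Gamma(3, 2) overlay curve: mode at (k-1) theta = 4
  t <- seq(0.1, 30, by = 0.1)
  curve <- gamma_pdf_scaled(t, 1, 3, 2)
  expect_equal(t[which.max(curve)], 4, tolerance = 0.11)
  expect_equal(gamma_pdf_scaled(0, 1, 3, 2), 0)
  expect_equal(gamma_pdf_scaled(2, 5, 3, 2), 5 * stats::dgamma(2, 3, scale = 2))
  expect_error(gamma_pdf_scaled(1, 1, -1, 2), "positive")
  expect_error(gamma_pdf_scaled(1, 1, 3, 0), "positive")
})

test_that("first-order matching formula and its limits", {
  # A = 0 collapses the denominator term: C = 1
  expect_equal(match_first_order(0, 0.01, 2), 1)
  # supplied evaluation time enters through t^k
  expect_equal(match_first_order(1, 0.5, 2, t = 4),
               4^0.5 / (2 * gamma(0.5) * 2^2.5 + 4^0.5))
  expect_warning(match_first_order(-1, 0.01, 2), "negative")
})

test_that("solve_A / threshold_from_gamma are exact inverses through C", {
  # algebraic special case: C = 1/2 gives A = 1 / (2 Gamma(k) theta^(k+2))
  k <- 0.05; theta <- 3
  grid <- expand.grid(m = c(3, 6, 60, 9), n = c(10, 100))
  grid <- grid[grid$m < grid$n, ]
  for (r in seq_len(nrow(grid))) {
    m <- grid$m[r]; n <- grid$n[r]
    A <- solve_A(m, n, k, theta)
    expect_equal(threshold_from_gamma(A, k, theta, n), m, tolerance = 1e-9)
    # and the recovered C round-trips to 1e-10
    expect_equal(match_first_order(A, k, theta), C_from_threshold(m, n),
                 tolerance = 1e-10)
  }
  # algebraic special case: any (m, n) with C = 1/2 would give
  # A = 1 / (2 Gamma(k) theta^(k+2)); check the inversion at the C level
  expect_equal(match_first_order(1 / (2 * gamma(k) * theta^(k + 2)), k, theta),
               0.5, tolerance = 1e-12)
})

test_that("first-order matching agrees with a numeric series expansion", {
  # Independent re-derivation: the linear-in-t coefficient of the gamma
  # density (after factoring t^(k-1)) is the quadratic Taylor coefficient of
  # exp(-t/theta) divided by theta^k Gamma(k); the linear coefficient of
  # A t C (1-C)^(t-1) is A C / (1-C). Solving the numeric matching for C
  # must reproduce the closed-form first-order estimate.
  for (k in c(0.01, 0.05)) {
    for (theta in c(1.5, 3)) {
      h <- 1e-4
      G <- function(t) exp(-t / theta)
      d2 <- (G(2 * h) - 2 * G(h) + G(0)) / h^2     # numeric G''(0)
      lhs_coef <- (d2 / 2) / (theta^k * gamma(k))  # coeff of t^(k+1)
      for (A in c(0.5, 2, 10)) {
        # numeric RHS linear coefficient: limit of A t C (1-C)^(t-1) / t
        C_numeric <- lhs_coef / (A + lhs_coef)     # solves A C/(1-C) = lhs
        C_closed <- match_first_order(A, k, theta)
        expect_equal(C_numeric, C_closed, tolerance = 0.05)
      }
    }
  }
})

test_that("recovered threshold is time-independent in the small-shape regime", {
  n <- 100
  theta <- 2
  variation <- vapply(c(0.1, 0.01, 0.001), function(k) {
    A <- solve_A(60, n, k, theta)
    mt <- vapply(seq(1, 10, by = 0.5), function(t) {
      suppressWarnings(threshold_from_gamma(A, k, theta, n, t = t))
    }, numeric(1))
    (max(mt) - min(mt)) / mean(mt)
  }, numeric(1))
  expect_true(all(diff(variation) < 0))  # variation shrinks with k
  # k = 0.01: < 1% variation over t in 1..5
  A <- solve_A(60, n, 0.01, theta)
  mt <- vapply(c(1, 2, 5), function(t) threshold_from_gamma(A, 0.01, theta, n, t = t),
               numeric(1))
  expect_lt((max(mt) - min(mt)) / mean(mt), 0.01)
})

test_that("threshold_from_gamma flags inconsistent parameters and large shapes", {
  expect_warning(threshold_from_gamma(1, 0.5, 2, 10), "small-shape")
  expect_error(
    suppressWarnings(threshold_from_gamma(-1, 0.01, 2, 10)),
    "outside"
  )
})

test_that("gamma MLE recovers known parameters from Gamma(3, 2) draws", {
  set.seed(1234)
  x <- stats::rgamma(1e4, shape = 3, scale = 2)
  fit <- fit_gamma(x)
  expect_gt(fit$k, 2.8); expect_lt(fit$k, 3.2)
  expect_gt(fit$theta, 1.87); expect_lt(fit$theta, 2.13)
  expect_lt(fit$ks_statistic, 0.02)
  expect_equal(fit$A, 1, tolerance = 0.15)  # histogram scale of a true density
  expect_equal(fit$censoring_fraction, 0)
})

test_that("degenerate samples are rejected; censored samples are dropped and logged", {
  expect_error(fit_gamma(rep(3, 100)), "equal")
  expect_error(fit_gamma(stats::rgamma(10, 2)), "at least 20")
  set.seed(2)
  x <- c(stats::rgamma(100, shape = 3, scale = 2), rep(NA_real_, 25))
  expect_message(fit <- fit_gamma(x), "censored")
  expect_equal(fit$n_used, 100L)
  expect_equal(fit$censoring_fraction, 0.2)
})

test_that("gamma fit of hitting times drawn from the theoretical law matches its mode", {
  # draw from the normalized law p(t) = t q^2 (1-q)^(t-1), t >= 1
  m <- 6; n <- 10
  q <- C_from_threshold(m, n)
  tgrid <- 1:2000
  pmf <- tgrid * q^2 * (1 - q)^(tgrid - 1)
  set.seed(77)
  x <- sample(tgrid, 1e4, replace = TRUE, prob = pmf)
  fit <- fit_gamma(x)
  gamma_mode <- (fit$k - 1) * fit$theta
  expect_lt(abs(gamma_mode - t_mode(m, n)) / t_mode(m, n), 0.2)
})
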