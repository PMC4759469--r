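#' Hitting time of a threshold component size
#'
#' The hitting time is the first recorded time at which the giant component
#' reaches at least `m` cells. For the monotone processes (models 1 and 2)
#' the giant component never shrinks, so this is a proper stopping time; if
#' the threshold is never reached within the recorded horizon the sample is
#' censored (never imputed) and the censoring time reported.
#'
#' @param traj a `raft_trajectory` (see [run_process()]), or any list with
#'   `times`, `giant_size` and `n_cells` fields.
#' @param m threshold component size, in `1:n_cells`.
#' @return A `hitting_time_sample`: list with `threshold_m`, `tau`
#'   (nonnegative integer, or `NA` when censored), `censored` (logical) and
#'   `censored_at` (last recorded time when censored, otherwise `NA`).
#' @examples
#' cfg <- process_config("model1", n_cells = 20, t_max = 200, seed = 7)
#' tr <- run_process(cfg)$trajectories[[1]]
#' hitting_time(tr, m = 5)
#' @export
hitting_time <- function(traj, m) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != as.integer(m)) {
    stop("`m` must be a single positive integer", call. = FALSE)
  }
  m <- as.integer(m)
  if (!is.null(traj$n_cells) && m > traj$n_cells) {
    stop("`m` must not exceed the number of cells", call. = FALSE)
  }
  hit <- which(traj$giant_size >= m)
  if (length(hit)) {
    out <- list(threshold_m = m, tau = traj$times[hit[1L]],
                censored = FALSE, censored_at = NA_integer_)
  } else {
    out <- list(threshold_m = m, tau = NA_integer_,
                censored = TRUE, censored_at = traj$times[length(traj$times)])
  }
  structure(out, class = "hitting_time_sample")
}

#' @export
print.hitting_time_sample <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<hitting_time_sample> m=%d: censored at t=%d\n",
                x$threshold_m, x$censored_at))
  } else {
    cat(sprintf("<hitting_time_sample> m=%d: tau=%d\n", x$threshold_m, x$tau))
  }
  invisible(x)
}

#' Hitting times of all replicates of a simulation
#'
#' @param sim a `raft_sim` from [run_process()].
#' @param m threshold component size; defaults to the configured
#'   `threshold_m`.
#' @return A data frame with columns `replicate`, `m`, `tau`, `censored`
#'   (0/1) and `censored_at`.
#' @export
hitting_times <- function(sim, m = NULL) {
  stopifnot(inherits(sim, "raft_sim"))
  if (is.null(m)) m <- sim$config$threshold_m
  rows <- lapply(sim$trajectories, function(tr) {
    h <- hitting_time(tr, m)
    data.frame(replicate = tr$replicate, m = h$threshold_m,
               tau = ifelse(h$censored, NA_integer_, h$tau),
               censored = as.integer(h$censored),
               censored_at = ifelse(h$censored, h$censored_at, NA_integer_))
  })
  do.call(rbind, rows)
}

#' Histogram of component sizes
#'
#' Counts components per size from a component-size multiset (an integer
#' vector, as stored in trajectory snapshots or in a
#' [connected_components()] decomposition). The conservation identity
#' `sum(size * count) == n_cells` holds for any full decomposition.
#'
#' @param sizes integer vector of component sizes, or a snapshot list with a
#'   `sizes` field.
#' @return A data frame with columns `size` and `count`, sorted by size.
#' @examples
#' component_size_histogram(c(3, 1, 1))
#' @export
component_size_histogram <- function(sizes) {
  if (is.list(sizes) && !is.null(sizes$sizes)) sizes <- sizes$sizes
  if (!length(sizes) || any(!is.finite(sizes)) || any(sizes < 1)) {
    stop("`sizes` must be a non-empty vector of positive component sizes",
         call. = FALSE)
  }
  tab <- table(as.integer(sizes))
  data.frame(size = as.integer(names(tab)), count = as.integer(tab))
}

#' Pointwise mean and standard deviation across replicates
#'
#' @param trajs a `raft_sim`, or a list of `raft_trajectory` objects sharing
#'   the same recorded times.
#' @return A data frame with column `t` and, for each recorded series
#'   (`edges`, `avg_degree`, `giant_size`), its pointwise mean and sd across
#'   replicates.
#' @export
summarize_replicates <- function(trajs) {
  if (inherits(trajs, "raft_sim")) trajs <- trajs$trajectories
  if (!length(trajs)) stop("need at least one trajectory", call. = FALSE)
  times <- trajs[[1L]]$times
  same <- vapply(trajs, function(tr) identical(tr$times, times), logical(1))
  if (!all(same)) {
    stop("trajectories have mismatched recorded times (unequal horizons?)",
         call. = FALSE)
  }
  out <- data.frame(t = times)
  for (series in c("edges", "avg_degree", "giant_size")) {
    mat <- vapply(trajs, function(tr) as.numeric(tr[[series]]),
                  numeric(length(times)))
    mat <- matrix(mat, nrow = length(times))
    out[[paste0(series, "_mean")]] <- rowMeans(mat)
    out[[paste0(series, "_sd")]] <-
      if (length(trajs) == 1L) 0 else apply(mat, 1L, stats::sd)
  }
  out
}
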