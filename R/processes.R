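#' Configure a raft-formation simulation run
#'
#' Bundles and validates the full specification of one simulation: which
#' update rule to use, the population size, the per-pair interaction
#' probability, the death probability, the horizon, the threshold component
#' size whose hitting time is tracked, the seed and the number of replicates.
#'
#' @param model `"model1"`, `"model2"` or `"model3"` (the integers 1:3 are
#'   also accepted). Model 1 draws one ordered candidate pair per timestep;
#'   Model 2 sweeps all pairs per timestep, creating each eligible edge with
#'   probability `p_edge`; Model 3 adds an independent death step in which
#'   each cell loses all its contacts with probability `p_death`.
#' @param n_cells positive integer, the number of cells (vertices).
#' @param p_edge per-pair interaction probability in `[0, 1]`; required for
#'   models 2 and 3.
#' @param p_death per-cell, per-timestep death probability in `[0, 1]`;
#'   required for model 3.
#' @param t_max nonnegative integer horizon (number of timesteps).
#' @param threshold_m threshold component size whose hitting time is
#'   recorded, in `1:n_cells`; defaults to `n_cells` (full convergence).
#' @param seed integer seed; per-replicate streams are derived from it.
#' @param replicates positive integer number of independent runs.
#' @param record_every record observables every this many timesteps (time 0
#'   and the final time are always recorded). The default 1 records every
#'   step.
#' @param snapshot_times integer times at which a full component-size
#'   snapshot (and the edge list) is stored.
#' @param stop_at_threshold stop a replicate as soon as the giant component
#'   reaches `threshold_m`.
#' @param stop_when_saturated stop when no eligible pair remains (models 1
#'   and 2; in model 3 death can always re-open pairs).
#' @return A validated `process_config`.
#' @examples
#' cfg <- process_config("model1", n_cells = 50, t_max = 200, seed = 1)
#' cfg
#' @export
process_config <- function(model,
                           n_cells,
                           p_edge = NULL,
                           p_death = NULL,
                           t_max,
                           threshold_m = NULL,
                           seed = 1L,
                           replicates = 1L,
                           record_every = 1L,
                           snapshot_times = integer(0),
                           stop_at_threshold = FALSE,
                           stop_when_saturated = FALSE) {
  if (is.numeric(model) && length(model) == 1L && model %in% 1:3) {
    model <- paste0("model", model)
  }
  model <- match.arg(model, c("model1", "model2", "model3"))
  chk_count <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
      stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
    }
    as.integer(x)
  }
  chk_prob <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
    }
    as.numeric(x)
  }
  n_cells <- chk_count(n_cells, "n_cells")
  t_max <- chk_count(t_max, "t_max", min = 0L)
  if (model %in% c("model2", "model3")) {
    if (is.null(p_edge)) stop("`p_edge` is required for models 2 and 3", call. = FALSE)
    p_edge <- chk_prob(p_edge, "p_edge")
  } else if (!is.null(p_edge)) {
    stop("`p_edge` is only meaningful for models 2 and 3", call. = FALSE)
  }
  if (model == "model3") {
    if (is.null(p_death)) stop("`p_death` is required for model 3", call. = FALSE)
    p_death <- chk_prob(p_death, "p_death")
  } else if (!is.null(p_death)) {
    stop("`p_death` is only meaningful for model 3", call. = FALSE)
  }
  if (is.null(threshold_m)) threshold_m <- n_cells
  threshold_m <- chk_count(threshold_m, "threshold_m")
  if (threshold_m > n_cells) {
    stop("`threshold_m` must not exceed `n_cells`", call. = FALSE)
  }
  seed <- chk_count(seed, "seed", min = -.Machine$integer.max)
  replicates <- chk_count(replicates, "replicates")
  record_every <- chk_count(record_every, "record_every")
  if (length(snapshot_times)) {
    snapshot_times <- vapply(snapshot_times, chk_count, integer(1),
                             name = "snapshot_times", min = 0L)
    if (any(snapshot_times > t_max)) {
      stop("`snapshot_times` must lie within [0, t_max]", call. = FALSE)
    }
    snapshot_times <- sort(unique(snapshot_times))
  }
  structure(
    list(
      model = model, n_cells = n_cells, p_edge = p_edge, p_death = p_death,
      t_max = t_max, threshold_m = threshold_m, seed = seed,
      replicates = replicates, record_every = record_every,
      snapshot_times = as.integer(snapshot_times),
      stop_at_threshold = isTRUE(stop_at_threshold),
      stop_when_saturated = isTRUE(stop_when_saturated)
    ),
    class = "process_config"
  )
}

#' @export
print.process_config <- function(x, ...) {
  cat(sprintf("<process_config> %s: N=%d, t_max=%d, m=%d, seed=%d, replicates=%d\n",
              x$model, x$n_cells, x$t_max, x$threshold_m, x$seed, x$replicates))
  if (!is.null(x$p_edge)) cat(sprintf("  p_edge=%g\n", x$p_edge))
  if (!is.null(x$p_death)) cat(sprintf("  p_death=%g\n", x$p_death))
  invisible(x)
}

#' Advance a cell graph by one timestep of a given model
#'
#' `step_model1` draws one ordered pair `(i, j)` uniformly from `{1..N}^2`
#' and applies [try_add_edge()]; at most one edge is added. `step_model2`
#' performs one full sweep over all unordered pairs in uniformly shuffled
#' order, creating each eligible edge with probability `p_edge` (degrees
#' update immediately, so an edge added earlier in the sweep can block a
#' later candidate). `step_model3` performs a Model 2 sweep followed by a
#' death sweep in which every cell independently loses all incident edges
#' with probability `p_death` (the cell itself remains and may reconnect
#' later).
#'
#' @param g a [cell_graph][make_empty_graph].
#' @param p_edge per-pair edge probability in `[0, 1]`.
#' @param p_death per-cell death probability in `[0, 1]`.
#' @return The updated `cell_graph`.
#' @examples
#' set.seed(1)
#' g <- make_empty_graph(10)
#' g <- step_model1(g)
#' g <- step_model2(g, p_edge = 0.5)
#' @export
step_model1 <- function(g) {
  stopifnot(inherits(g, "cell_graph"))
  st <- .st_from_graph(g)
  .st_step1(st)
  .st_to_graph(st)
}

#' @rdname step_model1
#' @export
step_model2 <- function(g, p_edge) {
  stopifnot(inherits(g, "cell_graph"))
  if (length(p_edge) != 1L || !is.finite(p_edge) || p_edge < 0 || p_edge > 1) {
    stop("`p_edge` must be a probability in [0, 1]", call. = FALSE)
  }
  st <- .st_from_graph(g)
  .st_sweep2(st, p_edge)
  .st_to_graph(st)
}

#' @rdname step_model1
#' @export
step_model3 <- function(g, p_edge, p_death) {
  stopifnot(inherits(g, "cell_graph"))
  for (p in list(p_edge, p_death)) {
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("`p_edge` and `p_death` must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  st <- .st_from_graph(g)
  .st_sweep3(st, p_edge, p_death)
  .st_to_graph(st)
}

#' Run a raft-formation process
#'
#' Starts each replicate from the empty graph on `n_cells` vertices, applies
#' the configured update rule `t_max` times and records the edge count,
#' average degree and giant-component size at the recorded times, plus full
#' component-size snapshots at `snapshot_times`. Per-replicate seeds are
#' derived deterministically from `(seed, replicate)`, so runs are
#' bit-reproducible.
#'
#' For Model 1 the run is advanced by exact geometric jump-chain embedding:
#' at any state, a timestep adds an edge with probability `2M/N^2` (where `M`
#' counts currently eligible pairs) and otherwise changes nothing, so the
#' waiting time to the next addition is Geometric and the added pair is
#' uniform among eligible pairs. This reproduces the per-draw chain exactly
#' while doing O(N) work instead of O(t_max).
#'
#' @param cfg a [process_config()].
#' @return A `raft_sim`: list with `config`, `rep_seeds` and `trajectories`
#'   (one `raft_trajectory` per replicate). Each trajectory carries the
#'   recorded series (`times`, `edges`, `avg_degree`, `giant_size`), the
#'   snapshots, the hitting time `tau` of `threshold_m` (NA when censored,
#'   with `censored_at` the last simulated time), `saturated_at` (time at
#'   which no eligible pair remained, if detected) and the final graph.
#' @examples
#' cfg <- process_config("model1", n_cells = 30, t_max = 300, threshold_m = 10,
#'                       seed = 42, replicates = 2)
#' sim <- run_process(cfg)
#' summary(sim)[1:3, ]
#' @export
run_process <- function(cfg) {
  if (!inherits(cfg, "process_config")) {
    stop("`cfg` must be a `process_config`", call. = FALSE)
  }
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$replicates)
  trajectories <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(rep_seeds[r])
    trajectories[[r]] <- .run_one(cfg, replicate = r, seed = rep_seeds[r])
  }
  structure(
    list(config = cfg, rep_seeds = rep_seeds, trajectories = trajectories),
    class = "raft_sim"
  )
}

# recorder shared by the per-model loops: preallocated series plus pointers
.rec_new <- function(cfg) {
  rt <- unique(sort(c(0L, seq.int(0L, cfg$t_max, by = cfg$record_every),
                      cfg$t_max, cfg$snapshot_times)))
  env <- new.env(parent = emptyenv())
  env$rt <- rt
  env$k <- 1L            # next recorded-time index to fill
  env$edges <- integer(length(rt))
  env$avg_degree <- numeric(length(rt))
  env$giant <- integer(length(rt))
  env$snap_at <- cfg$snapshot_times
  env$sk <- 1L
  env$snapshots <- list()
  env
}

# record the (constant) current state for all pending times <= upto_t
.rec_fill <- function(rec, upto_t, st, n, giant) {
  while (rec$k <= length(rec$rt) && rec$rt[rec$k] <= upto_t) {
    rec$edges[rec$k] <- st$ne
    rec$avg_degree[rec$k] <- 2 * st$ne / n
    rec$giant[rec$k] <- giant
    rec$k <- rec$k + 1L
  }
  while (rec$sk <= length(rec$snap_at) && rec$snap_at[rec$sk] <= upto_t) {
    snap <- .st_snapshot(st)
    rec$snapshots[[as.character(rec$snap_at[rec$sk])]] <- snap
    rec$sk <- rec$sk + 1L
  }
  invisible(rec)
}

.rec_truncate <- function(rec, last_t) {
  keep <- rec$rt <= last_t
  if (!any(rec$rt[keep] == last_t)) {
    # ensure the stopping time itself is present
    pos <- sum(keep)
    rec$rt <- c(rec$rt[keep], last_t)
    rec$edges <- c(rec$edges[keep], NA_integer_)
    rec$avg_degree <- c(rec$avg_degree[keep], NA_real_)
    rec$giant <- c(rec$giant[keep], NA_integer_)
    rec$k <- pos + 1L
  } else {
    rec$rt <- rec$rt[keep]
    rec$edges <- rec$edges[keep]
    rec$avg_degree <- rec$avg_degree[keep]
    rec$giant <- rec$giant[keep]
  }
  invisible(rec)
}

.run_one <- function(cfg, replicate, seed) {
  n <- cfg$n_cells
  m <- cfg$threshold_m
  st <- .st_new(n)
  rec <- .rec_new(cfg)
  tau <- if (1L >= m) 0L else NA_integer_
  saturated_at <- NA_integer_
  end_t <- cfg$t_max

  if (cfg$t_max == 0L || (cfg$stop_at_threshold && !is.na(tau))) {
    .rec_fill(rec, 0L, st, n, 1L)
    .rec_truncate(rec, 0L)
    end_t <- 0L
  } else if (cfg$model == "model1") {
    t <- 0L
    repeat {
      M <- .st_eligible_count(st)
      if (M < 1) {
        saturated_at <- t
        if (cfg$stop_when_saturated) {
          .rec_fill(rec, t, st, n, st$giant)
          .rec_truncate(rec, t)
          end_t <- t
        } else {
          .rec_fill(rec, cfg$t_max, st, n, st$giant)
        }
        break
      }
      w <- stats::rgeom(1L, min(1, 2 * M / (as.numeric(n)^2)))
      t_next <- t + w + 1
      if (t_next > cfg$t_max) {
        .rec_fill(rec, cfg$t_max, st, n, st$giant)
        break
      }
      .rec_fill(rec, t_next - 1, st, n, st$giant)   # pre-event plateau
      ab <- .st_pick_eligible(st, M)
      .st_add(st, ab[1L], ab[2L])
      t <- as.integer(t_next)
      .rec_fill(rec, t, st, n, st$giant)
      if (is.na(tau) && st$giant >= m) {
        tau <- t
        if (cfg$stop_at_threshold) {
          .rec_truncate(rec, t)
          end_t <- t
          break
        }
      }
    }
  } else {
    is_m3 <- cfg$model == "model3"
    .rec_fill(rec, 0L, st, n, 1L)   # empty-graph state at t = 0
    for (t in seq_len(cfg$t_max)) {
      if (is_m3) {
        .st_sweep3(st, cfg$p_edge, cfg$p_death)
      } else {
        .st_sweep2(st, cfg$p_edge)
      }
      need_record <- rec$k <= length(rec$rt) && rec$rt[rec$k] <= t
      giant <- if (!is_m3) st$giant
               else if (need_record || cfg$stop_at_threshold) .st_giant(st)
               else NA_integer_
      if (need_record) .rec_fill(rec, t, st, n, giant)
      if (is.na(tau) && !is.na(giant) && giant >= m) tau <- t
      if (!is.na(tau) && cfg$stop_at_threshold) {
        .rec_truncate(rec, t)
        end_t <- t
        break
      }
      if (cfg$stop_when_saturated && !is_m3 && .st_eligible_count(st) < 1) {
        saturated_at <- t
        .rec_truncate(rec, t)
        end_t <- t
        break
      }
      if (t == cfg$t_max) end_t <- t
    }
  }

  # fill any recorded values created by truncation
  if (anyNA(rec$edges)) {
    i <- which(is.na(rec$edges))
    rec$edges[i] <- st$ne
    rec$avg_degree[i] <- 2 * st$ne / n
    rec$giant[i] <- .st_giant(st)
  }
  structure(
    list(
      replicate = replicate,
      seed = seed,
      model = cfg$model,
      n_cells = n,
      threshold_m = m,
      times = rec$rt,
      edges = rec$edges,
      avg_degree = rec$avg_degree,
      giant_size = rec$giant,
      snapshots = rec$snapshots,
      tau = tau,
      censored = is.na(tau),
      censored_at = if (is.na(tau)) end_t else NA_integer_,
      saturated_at = saturated_at,
      final_graph = .st_to_graph(st)
    ),
    class = "raft_trajectory"
  )
}

#' @export
print.raft_trajectory <- function(x, ...) {
  cat(sprintf("<raft_trajectory> %s, N=%d, replicate %d: %d recorded times, final giant %d",
              x$model, x$n_cells, x$replicate, length(x$times),
              x$giant_size[length(x$giant_size)]))
  if (!is.na(x$tau)) cat(sprintf(", tau(m=%d)=%d", x$threshold_m, x$tau))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.raft_trajectory <- function(x, ...) {
  data.frame(
    replicate = x$replicate,
    t = x$times,
    edges = x$edges,
    avg_degree = x$avg_degree,
    giant_size = x$giant_size
  )
}

#' @export
print.raft_sim <- function(x, ...) {
  print(x$config)
  taus <- vapply(x$trajectories, function(tr) as.numeric(tr$tau), numeric(1))
  cat(sprintf("  %d replicate(s); hitting time of m=%d: %d reached, %d censored\n",
              length(x$trajectories), x$config$threshold_m,
              sum(!is.na(taus)), sum(is.na(taus))))
  invisible(x)
}

#' @export
as.data.frame.raft_sim <- function(x, ...) {
  do.call(rbind, lapply(x$trajectories, as.data.frame))
}

#' @export
summary.raft_sim <- function(object, ...) {
  summarize_replicates(object)
}

#' @export
plot.raft_sim <- function(x, which = c("giant_size", "avg_degree"), ...) {
  which <- match.arg(which)
  s <- summarize_replicates(x)
  ylab <- if (which == "giant_size") "giant component size" else "average degree"
  graphics::plot(s$t, s[[paste0(which, "_mean")]], type = "l",
                 xlab = "t", ylab = ylab, ...)
  invisible(x)
}
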