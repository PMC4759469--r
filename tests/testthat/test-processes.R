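test_that("process_config validates its fields", {
  expect_error(process_config("model2", n_cells = 10, t_max = 5), "p_edge")
  expect_error(process_config("model3", n_cells = 10, p_edge = 0.1, t_max = 5),
               "p_death")
  expect_error(process_config("model1", n_cells = 10, p_edge = 0.1, t_max = 5),
               "only meaningful")
  expect_error(process_config("model1", n_cells = 10, t_max = 5, threshold_m = 11),
               "threshold_m")
  expect_error(process_config("model2", n_cells = 10, p_edge = 1.5, t_max = 5),
               "probability")
  expect_error(process_config("model1", n_cells = 10, t_max = 5,
                              snapshot_times = 6), "snapshot_times")
  cfg <- process_config(1, n_cells = 10, t_max = 5)
  expect_s3_class(cfg, "process_config")
  expect_equal(cfg$model, "model1")
  expect_equal(cfg$threshold_m, 10L)  # defaults to full convergence
})

test_that("one Model 1 step adds a specific edge with probability 2/N^2", {
  set.seed(101)
  hits <- 0L
  reps <- 8000L
  g <- make_empty_graph(4)
  for (k in seq_len(reps)) {
    g1 <- step_model1(g)
    if (nrow(g1$edges) == 1L && g1$edges[1, 1] == 1L && g1$edges[1, 2] == 2L) {
      hits <- hits + 1L
    }
  }
  p_hat <- hits / reps
  se <- sqrt(0.125 * 0.875 / reps)
  expect_lt(abs(p_hat - 0.125), 4 * se)
})

test_that("a fully saturated graph is absorbing for Model 1", {
  g <- cycle_graph(4)
  set.seed(5)
  for (k in 1:25) expect_equal(step_model1(g)$edges, g$edges)
})

test_that("Model 2 sweeps obey the limiting cases", {
  g <- path_graph(5)
  set.seed(2)
  expect_equal(step_model2(g, 0)$edges, g$edges)
  # p = 1 on 3 empty vertices closes the triangle in a single sweep,
  # whatever the visit order
  for (s in 1:10) {
    set.seed(s)
    tri <- step_model2(make_empty_graph(3), 1)
    expect_equal(tri$degree, c(2L, 2L, 2L))
    expect_equal(nrow(tri$edges), 3L)
  }
})

test_that("first Model 2 sweep on an empty graph adds ~ Binomial(N(N-1)/2, P) edges", {
  cfg <- process_config("model2", n_cells = 1000, p_edge = 1e-4, t_max = 1,
                        seed = 31, replicates = 10)
  sim <- run_process(cfg)
  edges <- vapply(sim$trajectories, function(tr) tr$edges[length(tr$edges)],
                  integer(1))
  expected <- 1e-4 * 1000 * 999 / 2  # 49.95; cap collisions contribute < 1%
  se <- sqrt(expected) / sqrt(10)
  expect_lt(abs(mean(edges) - expected), 4 * se)
})

test_that("Model 3 reduces to Model 2 at p_death = 0 and empties at p_death = 1, p_edge = 0", {
  set.seed(9)
  g <- make_empty_graph(40)
  # p_death = 0: same distribution as a Model 2 sweep; compare means
  e2 <- replicate(300, nrow(step_model2(g, 0.05)$edges))
  e3 <- replicate(300, nrow(step_model3(g, 0.05, 0)$edges))
  expect_lt(abs(mean(e2) - mean(e3)), 4 * sqrt(var(e2) / 300 + var(e3) / 300))
  # certain death with no edge creation removes everything
  full <- cycle_graph(6)
  dead <- step_model3(full, 0, 1)
  expect_equal(nrow(dead$edges), 0L)
  expect_equal(dead$degree, rep(0L, 6))
})

test_that("cell death zeroes the row and column of the dead cell only", {
  tri <- cycle_graph(3)
  st <- swarmraft:::.st_from_graph(tri)
  swarmraft:::.st_kill(st, 2L)
  g <- swarmraft:::.st_to_graph(st)
  expect_equal(g$edges, matrix(c(1L, 3L), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))))
  expect_equal(g$degree, c(1L, 0L, 1L))
})

test_that("trajectories are monotone for models 1-2 and respect invariants", {
  for (model in c("model1", "model2")) {
    cfg <- process_config(model, n_cells = 60,
                          p_edge = if (model == "model2") 0.002 else NULL,
                          t_max = 120, seed = 13, replicates = 3)
    sim <- run_process(cfg)
    for (tr in sim$trajectories) {
      expect_length(tr$times, cfg$t_max + 1L)   # record_every = 1
      expect_true(all(diff(tr$edges) >= 0))
      expect_true(all(diff(tr$giant_size) >= 0))
      expect_true(all(tr$avg_degree >= 0 & tr$avg_degree <= 2))
      # Model 1 adds at most one edge per step
      if (model == "model1") expect_true(all(diff(tr$edges) <= 1))
      expect_true(all(tr$final_graph$degree <= 2L))
      expect_equal(tr$edges[1], 0L)
      expect_equal(tr$giant_size[1], 1L)
    }
  }
})

test_that("degree cap and adjacency symmetry hold after every step of every model", {
  set.seed(23)
  for (model in 1:3) {
    g <- make_empty_graph(25)
    for (t in 1:40) {
      g <- switch(model, step_model1(g), step_model2(g, 0.02),
                  step_model3(g, 0.02, 0.05))
      expect_true(all(g$degree <= 2L))
      expect_equal(g$degree, tabulate(g$edges, nbins = 25))
      if (nrow(g$edges)) {
        expect_true(all(g$edges[, 1] < g$edges[, 2]))
        expect_false(any(duplicated(g$edges)))
      }
    }
  }
})

test_that("Model 2 giant growth is stochastically increasing in P", {
  giant_at <- function(p, seed) {
    cfg <- process_config("model2", n_cells = 100, p_edge = p, t_max = 50,
                          seed = seed, replicates = 10, record_every = 50)
    sim <- run_process(cfg)
    mean(vapply(sim$trajectories,
                function(tr) tr$giant_size[length(tr$giant_size)], integer(1)))
  }
  expect_gt(giant_at(2e-3, 77), giant_at(2e-4, 78))
})

test_that("run_process is bit-reproducible from (seed, replicate) and t_max = 0 works", {
  cfg <- process_config("model2", n_cells = 30, p_edge = 0.01, t_max = 40,
                        seed = 99, replicates = 2)
  s1 <- run_process(cfg)
  s2 <- run_process(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(s1$trajectories[[2]]$final_graph,
                   s2$trajectories[[2]]$final_graph)
  cfg0 <- process_config("model1", n_cells = 4, t_max = 0, seed = 1)
  tr0 <- run_process(cfg0)$trajectories[[1]]
  expect_equal(tr0$times, 0L)
  expect_equal(tr0$edges, 0L)
  expect_equal(tr0$giant_size, 1L)
})

test_that("run_process stepping agrees in distribution with repeated step_model2 calls", {
  # same chain realised two ways: the optimized runner vs the public stepper
  n <- 20; p <- 0.05; t_max <- 10; reps <- 400
  set.seed(55)
  via_steps <- replicate(reps, {
    g <- make_empty_graph(n)
    for (t in seq_len(t_max)) g <- step_model2(g, p)
    connected_components(g)$giant_size
  })
  cfg <- process_config("model2", n_cells = n, p_edge = p, t_max = t_max,
                        seed = 56, replicates = reps, record_every = t_max)
  via_run <- vapply(run_process(cfg)$trajectories,
                    function(tr) tr$giant_size[length(tr$giant_size)], integer(1))
  se <- sqrt(var(via_steps) / reps + var(via_run) / reps)
  expect_lt(abs(mean(via_steps) - mean(via_run)), 4 * se)
})

test_that("Model 1 saturation stop yields average degree ~ 2 and a terminal state", {
  cfg <- process_config("model1", n_cells = 100, t_max = 200000, seed = 3,
                        replicates = 2, record_every = 1000,
                        stop_when_saturated = TRUE)
  sim <- run_process(cfg)
  for (tr in sim$trajectories) {
    final_deg <- tr$avg_degree[length(tr$avg_degree)]
    expect_gt(final_deg, 1.9)
    if (!is.na(tr$saturated_at)) {
      # terminal state: at most two open slots and they must be adjacent
      open <- which(tr$final_graph$degree < 2L)
      expect_lte(length(open), 2L)
    }
  }
})
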