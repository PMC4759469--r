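#' Reproduce the package's reference figure set
#'
#' Runs the documented configuration behind each figure in the package's
#' reference set (average-degree saturation and giant-component
#' engulfing under Model 1; Model 2 convergence, its dependence on the
#' interaction probability `P`, and component-size distributions at
#' `t = 500`; Model 3 non-convergence under cell death; the theoretical
#' hitting curve and its cumulative form for `m = 6, n = 10`) and writes the
#' underlying data as CSV plus a rendered PDF plot.
#'
#' At `scale = "full"` the stochastic figures use `N = 1000` cells and 10
#' replicates; `scale = "reduced"` uses `N = 200` and 3 replicates for quick
#' desk-scale runs. Model 2/3 simulations use the interaction probability
#' `P = 1e-4` where the figure does not sweep `P`. The Model 3 death-rate
#' grid `p_D` in \{0.001, 0.01, 0.1\} is this package's documented choice.
#'
#' @param figure integer figure id in `2:10`.
#' @param scale `"full"` or `"reduced"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, a list with `files` (paths written) and `data`.
#' @export
reproduce_figure <- function(figure, scale = c("full", "reduced"),
                             out_dir = ".", seed = 1L) {
  if (length(figure) != 1L || !is.finite(figure) || !(figure %in% 2:10)) {
    stop("`figure` must be an integer in 2..10", call. = FALSE)
  }
  scale <- match.arg(scale)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  N <- if (scale == "full") 1000L else 200L
  reps <- if (scale == "full") 10L else 3L
  P_default <- 1e-4
  P_grid <- c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2)
  pD_grid <- c(0.001, 0.01, 0.1)
  files <- character(0)
  pfx <- file.path(out_dir, sprintf("fig%d_%s", figure, scale))
  data <- NULL

  write_traj <- function(sim, path) {
    utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
    path
  }

  if (figure %in% c(2L, 3L)) {
    cfg <- process_config("model1", n_cells = N, t_max = 10000L, seed = seed,
                          replicates = reps, record_every = 10L)
    sim <- run_process(cfg)
    data <- summarize_replicates(sim)
    files <- c(files, write_traj(sim, paste0(pfx, "_trajectory.csv")))
    ycol <- if (figure == 2L) "avg_degree_mean" else "giant_size_mean"
    ylab <- if (figure == 2L) "average degree" else "giant component size"
    grDevices::pdf(paste0(pfx, ".pdf"), width = 6, height = 4)
    graphics::plot(data$t, data[[ycol]], type = "l", xlab = "t", ylab = ylab,
                   main = sprintf("Model 1, N = %d (%d replicates)", N, reps))
    if (figure == 2L) graphics::abline(h = 2, lty = 2)
    grDevices::dev.off()
    files <- c(files, paste0(pfx, ".pdf"))
  } else if (figure %in% c(4L, 5L)) {
    cfg <- process_config("model2", n_cells = N, p_edge = P_default,
                          t_max = 2000L, seed = seed, replicates = reps,
                          record_every = 5L)
    sim <- run_process(cfg)
    data <- summarize_replicates(sim)
    files <- c(files, write_traj(sim, paste0(pfx, "_trajectory.csv")))
    ycol <- if (figure == 4L) "avg_degree_mean" else "giant_size_mean"
    ylab <- if (figure == 4L) "average degree" else "giant component size"
    grDevices::pdf(paste0(pfx, ".pdf"), width = 6, height = 4)
    graphics::plot(data$t, data[[ycol]], type = "l", xlab = "t", ylab = ylab,
                   main = sprintf("Model 2, N = %d, P = %g", N, P_default))
    grDevices::dev.off()
    files <- c(files, paste0(pfx, ".pdf"))
  } else if (figure %in% c(6L, 7L)) {
    per_p <- lapply(seq_along(P_grid), function(ip) {
      cfg <- process_config("model2", n_cells = N, p_edge = P_grid[ip],
                            t_max = 500L, seed = seed + ip, replicates = reps,
                            snapshot_times = 500L)
      run_process(cfg)
    })
    if (figure == 6L) {
      data <- do.call(rbind, lapply(seq_along(P_grid), function(ip) {
        s <- summarize_replicates(per_p[[ip]])
        s$P <- P_grid[ip]
        s
      }))
      files <- c(files, {
        path <- paste0(pfx, "_trajectory.csv")
        utils::write.csv(data, path, row.names = FALSE)
        path
      })
      grDevices::pdf(paste0(pfx, ".pdf"), width = 6, height = 4)
      graphics::matplot(
        matrix(data$t, ncol = length(P_grid)),
        matrix(data$giant_size_mean, ncol = length(P_grid)),
        type = "l", lty = 1, xlab = "t", ylab = "giant component size",
        main = sprintf("Model 2, N = %d", N))
      graphics::legend("topleft", legend = sprintf("P = %g", P_grid),
                       col = seq_along(P_grid), lty = 1, cex = 0.7)
      grDevices::dev.off()
      files <- c(files, paste0(pfx, ".pdf"))
    } else {
      data <- do.call(rbind, lapply(seq_along(P_grid), function(ip) {
        sim <- per_p[[ip]]
        do.call(rbind, lapply(sim$trajectories, function(tr) {
          h <- component_size_histogram(tr$snapshots[["500"]])
          data.frame(P = P_grid[ip], replicate = tr$replicate, t = 500L,
                     size = h$size, count = h$count)
        }))
      }))
      path <- paste0(pfx, "_components_t500.csv")
      utils::write.csv(data, path, row.names = FALSE)
      files <- c(files, path)
      grDevices::pdf(paste0(pfx, ".pdf"), width = 8, height = 5)
      graphics::par(mfrow = c(2, 3))
      for (p in P_grid) {
        d <- data[data$P == p, ]
        agg <- stats::aggregate(count ~ size, data = d, FUN = mean)
        graphics::barplot(agg$count, names.arg = agg$size,
                          xlab = "component size", ylab = "mean count",
                          main = sprintf("P = %g", p))
      }
      grDevices::dev.off()
      files <- c(files, paste0(pfx, ".pdf"))
    }
  } else if (figure == 8L) {
    data <- do.call(rbind, lapply(seq_along(pD_grid), function(ip) {
      cfg <- process_config("model3", n_cells = N, p_edge = P_default,
                            p_death = pD_grid[ip], t_max = 10000L,
                            seed = seed + ip, replicates = reps,
                            record_every = 50L)
      s <- summarize_replicates(run_process(cfg))
      s$p_death <- pD_grid[ip]
      s
    }))
    path <- paste0(pfx, "_trajectory.csv")
    utils::write.csv(data, path, row.names = FALSE)
    files <- c(files, path)
    grDevices::pdf(paste0(pfx, ".pdf"), width = 6, height = 4)
    graphics::matplot(
      matrix(data$t, ncol = length(pD_grid)),
      matrix(data$giant_size_mean, ncol = length(pD_grid)),
      type = "l", lty = 1, xlab = "t", ylab = "giant component size",
      main = sprintf("Model 3, N = %d, P = %g", N, P_default))
    graphics::legend("topleft", legend = sprintf("p_D = %g", pD_grid),
                     col = seq_along(pD_grid), lty = 1, cex = 0.7)
    grDevices::dev.off()
    files <- c(files, paste0(pfx, ".pdf"))
  } else if (figure == 9L) {
    t <- 1:100
    data <- data.frame(
      t = t,
      pdf = hitting_pdf(t, 6, 10),
      pdf_normalized = C_from_threshold(6, 10) * hitting_pdf(t, 6, 10),
      gamma_3_2 = gamma_pdf_scaled(t, A = 1, k = 3, theta = 2)
    )
    path <- paste0(pfx, ".csv")
    utils::write.csv(data, path, row.names = FALSE)
    files <- c(files, path)
    grDevices::pdf(paste0(pfx, ".pdf"), width = 6, height = 4)
    graphics::plot(data$t, data$pdf, type = "l", xlab = "t",
                   ylab = "hitting curve",
                   main = "Hitting curve, m = 6, n = 10")
    graphics::lines(data$t, data$gamma_3_2 / max(data$gamma_3_2) * max(data$pdf),
                    lty = 2)
    graphics::legend("topright", legend = c("t q (1-q)^(t-1)",
                                            "Gamma(3, 2), rescaled"),
                     lty = 1:2, cex = 0.7)
    grDevices::dev.off()
    files <- c(files, paste0(pfx, ".pdf"))
  } else if (figure == 10L) {
    t <- 1:1000
    data <- data.frame(t = t, cdf = hitting_cdf(t, 6, 10))
    path <- paste0(pfx, ".csv")
    utils::write.csv(data, path, row.names = FALSE)
    files <- c(files, path)
    grDevices::pdf(paste0(pfx, ".pdf"), width = 6, height = 4)
    graphics::plot(data$t, data$cdf, type = "l", xlab = "t",
                   ylab = "cumulative hitting probability",
                   main = "Cumulative hitting curve, m = 6, n = 10")
    grDevices::dev.off()
    files <- c(files, paste0(pfx, ".pdf"))
  }

  manifest <- list(
    figure = figure, scale = scale, seed = seed,
    package_version = as.character(utils::packageVersion("swarmraft")),
    outputs = files
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    mpath <- paste0(pfx, "_manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, mpath)
  }
  invisible(list(files = files, data = data))
}
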