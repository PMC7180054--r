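#' Run one full simulation
#'
#' Initializes `n_receptors` free receptors uniformly over the rectangle,
#' advances the ensemble through an unrecorded burn-in (duration
#' `config$t_burn_in`, which should comfortably exceed the slowest kinetic
#' relaxation time `1/k_off`), then through the recorded baseline and
#' post-induction phases, sampling per-synapse receptor counts every
#' `sample_interval` seconds. Recording time zero is the start of the
#' baseline.
#'
#' @param config a [sim_config()].
#' @param schedule a [kinetic_schedule()] covering
#'   `[-t_burn_in, t_baseline + t_post)`; a [protocol_spec][protocol()] is
#'   also accepted and resolved via [make_schedule()].
#' @param seed RNG seed for this run (default `config$seed`).
#' @param record_occupancy if `TRUE`, also accumulate a time-averaged spatial
#'   occupancy grid (receptors per bin, averaged over the steps of
#'   `occupancy_window`).
#' @param occupancy_bin grid bin size, um; must tile both region dimensions
#'   exactly. Default 0.05 um resolves a 0.3 um synapse into 6 x 6 bins.
#' @param occupancy_window time window `c(from, to)` (s, recording clock)
#'   over which the grid accumulates; default the whole recorded span.
#' @return object of class `ampar_sim`: sampled `times`, integer matrices
#'   `bound` and `total` (time x synapse), integer vector `extra`, the final
#'   receptor ensemble, and (optionally) an `occupancy` grid.
#' @examples
#' cfg <- sim_config(n_receptors = 100, t_burn_in = 20, t_baseline = 20,
#'                   t_post = 40)
#' sim <- run_simulation(cfg, protocol("basal"), seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(config, schedule, seed = config$seed,
                           record_occupancy = FALSE, occupancy_bin = 0.05,
                           occupancy_window = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(schedule, "protocol_spec")) {
    schedule <- make_schedule(schedule, config)
  }
  stopifnot(inherits(schedule, "kinetic_schedule"))

  dt <- config$dt
  t_end <- config$t_baseline + config$t_post
  n_steps <- round((config$t_burn_in + t_end) / dt)
  # rates in force during step k govern (t_{k-1}, t_k]; evaluated at t_{k-1}
  step_start <- -config$t_burn_in + (seq_len(n_steps) - 1) * dt
  rates <- tryCatch(rate_at(schedule, step_start), error = function(e) {
    stop("schedule does not span burn-in + baseline + post phases",
         call. = FALSE)
  })
  p_bind <- pmin(rates$k_on * dt, 1)
  p_unbind <- pmin(rates$k_off * dt, 1)

  times <- seq(0, t_end, by = config$sample_interval)
  sample_steps <- as.integer(round((times + config$t_burn_in) / dt))

  occ_nx <- occ_ny <- 0L
  occ_from <- occ_to <- 0L
  if (record_occupancy) {
    occ_nx <- config$region_length / occupancy_bin
    occ_ny <- config$region_width / occupancy_bin
    if (abs(occ_nx - round(occ_nx)) > 1e-9 || abs(occ_ny - round(occ_ny)) > 1e-9) {
      stop("occupancy_bin must tile both region dimensions exactly",
           call. = FALSE)
    }
    occ_nx <- as.integer(round(occ_nx))
    occ_ny <- as.integer(round(occ_ny))
    if (is.null(occupancy_window)) occupancy_window <- c(0, t_end)
    occ_from <- as.integer(max(1, round((occupancy_window[1] + config$t_burn_in) / dt)))
    occ_to <- as.integer(round((occupancy_window[2] + config$t_burn_in) / dt))
  }

  syn <- config$synapses
  set.seed(seed)
  ens <- init_ensemble(config)

  res <- .engine_run(ens$x, ens$y, rep(-1L, config$n_receptors),
                     syn$center_x, syn$center_y, syn$side / 2,
                     config$region_length, config$region_width,
                     config$D_out, config$D_in, config$D_trap,
                     config$p_crossing,
                     match(config$crossing_mode, c("symmetric", "entry", "exit")) - 1L,
                     match(config$bound_edge, c("hold", "reflect")) - 1L,
                     dt, p_bind, p_unbind, sample_steps,
                     record_occupancy, occ_nx, occ_ny, occupancy_bin,
                     occ_from, occ_to)

  colnames(res$bound) <- colnames(res$total) <- syn$id
  occupancy <- NULL
  if (record_occupancy) {
    occupancy <- structure(list(grid = res$occupancy, bin_size = occupancy_bin,
                                window = occupancy_window),
                           class = "occupancy_grid")
  }
  bs <- rep(NA_integer_, config$n_receptors)
  is_b <- res$bound_synapse >= 0
  bs[is_b] <- syn$id[res$bound_synapse[is_b] + 1L]
  final <- data.frame(x = res$x, y = res$y, bound = is_b, bound_synapse = bs)
  structure(list(times = times, bound = res$bound, total = res$total,
                 extra = res$extra, ensemble = final, config = config,
                 schedule = schedule, seed = seed, occupancy = occupancy),
            class = "ampar_sim")
}

#' @export
print.ampar_sim <- function(x, ...) {
  cat(sprintf(
    "AMPAR diffusion-trapping simulation: %d receptors, %d synapses, %d samples over %g s (seed %d)\n",
    x$config$n_receptors, ncol(x$total), length(x$times),
    max(x$times), x$seed))
  invisible(x)
}

#' @export
summary.ampar_sim <- function(object, ...) {
  base <- object$times <= object$config$t_baseline
  per_syn <- rowMeans(object$total)
  cat("AMPAR diffusion-trapping simulation\n")
  print(object$config)
  cat(sprintf("  baseline mean receptors/synapse : %.2f\n",
              mean(per_syn[base])))
  cat(sprintf("  final mean receptors/synapse    : %.2f\n",
              per_syn[length(per_syn)]))
  cat(sprintf("  final extra-synaptic receptors  : %d\n",
              object$extra[length(object$extra)]))
  invisible(object)
}

#' @export
as.data.frame.ampar_sim <- function(x, ..., replicate = 1L) {
  ns <- ncol(x$total)
  nt <- length(x$times)
  data.frame(
    time_s = c(rep(x$times, ns), x$times),
    replicate = replicate,
    synapse_id = c(rep(colnames(x$total), each = nt), rep("extra", nt)),
    n_bound = c(as.vector(x$bound), rep(NA_integer_, nt)),
    n_total = c(as.vector(x$total), x$extra),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.ampar_sim <- function(x, ...) {
  per_syn <- rowMeans(x$total)
  graphics::plot(x$times / 60, per_syn, type = "l", xlab = "time (min)",
                 ylab = "receptors per synapse (mean over synapses)", ...)
  graphics::abline(v = x$config$t_baseline / 60, lty = 2, col = "grey40")
  invisible(x)
}

#' Run a set of replicate simulations
#'
#' Runs `n_replicates` independent simulations of one protocol, replicate `r`
#' seeded with `base_seed + r - 1`, and summarizes the per-synapse receptor
#' count (each run's mean over its synapses) across replicates: per-time mean
#' and standard error of the mean (SEM, denominator `n_replicates`).
#'
#' @param config a [sim_config()].
#' @param spec a [protocol_spec][protocol()] or a prebuilt
#'   [kinetic_schedule()].
#' @param n_replicates number of replicate runs (default 10).
#' @param base_seed seed of the first replicate (default `config$seed`).
#' @return object of class `replicate_set`: `times`, matrix `rep_series`
#'   (time x replicate, per-synapse mean counts), `mean`, `sem` (NA when
#'   `n_replicates == 1`), arrays `bound` and `total`
#'   (time x synapse x replicate), matrix `extra`, `seeds`, plus the config
#'   and spec.
#' @examples
#' cfg <- sim_config(n_receptors = 100, t_burn_in = 20, t_baseline = 20,
#'                   t_post = 40)
#' rs <- run_replicates(cfg, protocol("basal"), n_replicates = 2, base_seed = 1)
#' head(summary_table(rs))
#' @export
run_replicates <- function(config, spec, n_replicates = 10,
                           base_seed = config$seed) {
  stopifnot(n_replicates >= 1)
  schedule <- if (inherits(spec, "protocol_spec")) {
    make_schedule(spec, config)
  } else {
    spec
  }
  seeds <- as.integer(base_seed + seq_len(n_replicates) - 1L)
  sims <- lapply(seeds, function(s) run_simulation(config, schedule, seed = s))

  nt <- length(sims[[1]]$times)
  ns <- ncol(sims[[1]]$total)
  total <- array(0L, dim = c(nt, ns, n_replicates))
  bound <- array(0L, dim = c(nt, ns, n_replicates))
  extra <- matrix(0L, nt, n_replicates)
  for (r in seq_len(n_replicates)) {
    stopifnot(all(rowSums(sims[[r]]$total) + sims[[r]]$extra ==
                    config$n_receptors))
    total[, , r] <- sims[[r]]$total
    bound[, , r] <- sims[[r]]$bound
    extra[, r] <- sims[[r]]$extra
  }
  rep_series <- apply(total, 3, rowMeans)  # time x replicate
  m <- rowMeans(rep_series)
  sem <- if (n_replicates > 1) {
    apply(rep_series, 1, stats::sd) / sqrt(n_replicates)
  } else {
    rep(NA_real_, nt)
  }
  structure(list(times = sims[[1]]$times, rep_series = rep_series,
                 mean = m, sem = sem, bound = bound, total = total,
                 extra = extra, seeds = seeds, config = config,
                 spec = if (inherits(spec, "protocol_spec")) spec else NULL,
                 schedule = schedule),
            class = "replicate_set")
}

#' Cross-replicate summary table
#'
#' @param x a [replicate_set][run_replicates()].
#' @return data.frame with `time_s`, `mean_count`, `sem_count`.
#' @export
summary_table <- function(x) {
  stopifnot(inherits(x, "replicate_set"))
  data.frame(time_s = x$times, mean_count = x$mean, sem_count = x$sem)
}

#' @export
print.replicate_set <- function(x, ...) {
  nm <- if (!is.null(x$spec)) x$spec$name else "custom schedule"
  cat(sprintf(
    "Replicate set: %d runs of '%s' (seeds %d..%d)\n", ncol(x$rep_series),
    nm, min(x$seeds), max(x$seeds)))
  base <- x$times <= x$config$t_baseline
  cat(sprintf("  baseline receptors/synapse: %.2f (SEM %.2f)\n",
              mean(x$mean[base]),
              stats::sd(colMeans(x$rep_series[base, , drop = FALSE])) /
                sqrt(ncol(x$rep_series))))
  invisible(x)
}

#' @export
as.data.frame.replicate_set <- function(x, ...) {
  ns <- dim(x$total)[2]
  nt <- length(x$times)
  nr <- dim(x$total)[3]
  do.call(rbind, lapply(seq_len(nr), function(r) {
    data.frame(
      time_s = c(rep(x$times, ns), x$times),
      replicate = r,
      synapse_id = c(rep(colnames(x$total) %||% as.character(seq_len(ns)),
                         each = nt), rep("extra", nt)),
      n_bound = c(as.vector(x$bound[, , r]), rep(NA_integer_, nt)),
      n_total = c(as.vector(x$total[, , r]), x$extra[, r]),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
plot.replicate_set <- function(x, normalized = FALSE, ...) {
  if (normalized) {
    v <- percent_of_baseline(x)
    ylab <- "receptors per synapse (% of baseline)"
  } else {
    v <- x$mean
    ylab <- "receptors per synapse"
  }
  graphics::plot(x$times / 60, v, type = "l", xlab = "time (min)",
                 ylab = ylab, ...)
  graphics::abline(v = x$config$t_baseline / 60, lty = 2, col = "grey40")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
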