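#' Closed-form steady-state enrichment ratio
#'
#' Steady-state ratio of synaptic to extra-synaptic receptor density,
#' `p_crossing * (D_out / D_in) * (1 + k_on / k_off)`: the barrier and the
#' diffusivity contrast set the free-receptor density ratio across the
#' border, and the kinetic factor `1 + k_on/k_off` adds the scaffold-bound
#' pool on top of the free synaptic pool. With zero `k_off` and positive
#' `k_on` the trap is irreversible and the ratio is returned as `Inf` with a
#' warning (the whole closed population ends up bound).
#'
#' @param p_crossing border-crossing probability.
#' @param D_out,D_in diffusion coefficients, um^2/s (`D_in > 0`).
#' @param k_on,k_off binding/unbinding rates, 1/s.
#' @return the enrichment ratio (dimensionless).
#' @examples
#' enrichment_ratio(0.5, 0.1, 0.05, 1, 0.04)  # 26 at the default parameters
#' @export
enrichment_ratio <- function(p_crossing, D_out, D_in, k_on, k_off) {
  stopifnot(D_in > 0, p_crossing >= 0, p_crossing <= 1, D_out >= 0,
            k_on >= 0, k_off >= 0)
  if (k_on > 0 && k_off == 0) {
    warning("k_off = 0 with positive k_on: irreversible trapping, ",
            "enrichment is unbounded", call. = FALSE)
    return(Inf)
  }
  kin <- if (k_on == 0) 1 else 1 + k_on / k_off
  p_crossing * (D_out / D_in) * kin
}

#' Per-synapse receptor count implied by an enrichment ratio
#'
#' Conservation accounting around the enrichment ratio: with a closed
#' population `N = rho_out * A_out + ratio * rho_out * A_syn` the
#' extra-synaptic density `rho_out` is solved for, and the implied count per
#' synapse is `ratio * rho_out * side^2`. With unequal synapse sizes a vector
#' is returned (one count per synapse).
#'
#' @param config a [sim_config()].
#' @param ratio enrichment ratio, e.g. from [enrichment_ratio()]. `Inf` gives
#'   the saturation ceiling `n_receptors` split over the synapses.
#' @return predicted receptors per synapse (numeric scalar, or vector when
#'   synapse sizes differ).
#' @examples
#' predicted_basal_count(sim_config(), 1)   # area-proportional: 4.5
#' predicted_basal_count(sim_config(), 26)  # approx 75 at defaults
#' @export
predicted_basal_count <- function(config, ratio) {
  stopifnot(inherits(config, "sim_config"), ratio >= 0)
  a_syn <- config$synapses$side^2
  a_out <- config$region_length * config$region_width - sum(a_syn)
  if (a_out + sum(a_syn) <= 0) stop("zero total area", call. = FALSE)
  if (is.infinite(ratio)) {
    counts <- config$n_receptors * a_syn / sum(a_syn)
  } else {
    rho_out <- config$n_receptors / (a_out + ratio * sum(a_syn))
    counts <- ratio * rho_out * a_syn
  }
  if (length(unique(a_syn)) == 1) counts[1] else counts
}

#' Normalize a series to its baseline mean
#'
#' Expresses a receptor-count series as a percentage of its mean over the
#' baseline window, the normalization used for potentiation curves. For a
#' [replicate_set][run_replicates()] the replicate-mean series is normalized
#' (set `per_replicate = TRUE` to normalize each replicate by its own
#' baseline first and then average).
#'
#' @param x numeric series, or a `replicate_set`.
#' @param times sample times (s); taken from the object when `x` is a
#'   `replicate_set`.
#' @param baseline_window `c(from, to)` in s; defaults to the configured
#'   baseline for a `replicate_set` and must be given otherwise.
#' @param per_replicate see above.
#' @param ... unused.
#' @return numeric series in percent (100 = baseline level).
#' @export
percent_of_baseline <- function(x, ...) UseMethod("percent_of_baseline")

#' @rdname percent_of_baseline
#' @export
percent_of_baseline.default <- function(x, times, baseline_window, ...) {
  sel <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  b <- mean(x[sel])
  if (b == 0) stop("baseline mean is zero: normalization undefined",
                   call. = FALSE)
  100 * x / b
}

#' @rdname percent_of_baseline
#' @export
percent_of_baseline.replicate_set <- function(x, baseline_window = NULL,
                                              per_replicate = FALSE, ...) {
  if (is.null(baseline_window)) baseline_window <- c(0, x$config$t_baseline)
  if (per_replicate) {
    norm <- apply(x$rep_series, 2, percent_of_baseline.default,
                  times = x$times, baseline_window = baseline_window)
    rowMeans(norm)
  } else {
    percent_of_baseline.default(x$mean, x$times, baseline_window)
  }
}

#' Plateau level of a normalized series
#'
#' @param normalized series in percent of baseline.
#' @param times sample times, s.
#' @param plateau_window `c(from, to)` in s.
#' @return mean of the series over the window, in percent.
#' @export
plateau_level <- function(normalized, times, plateau_window) {
  sel <- times >= plateau_window[1] & times <= plateau_window[2]
  if (!any(sel)) stop("plateau window contains no samples", call. = FALSE)
  mean(normalized[sel])
}

#' Baseline and plateau quantification of a replicate set
#'
#' Computes the baseline-window mean per-synapse count, the plateau-window
#' mean, and the plateau as a percentage of baseline, from the
#' replicate-mean series. The default plateau window is the final 5 minutes
#' of the recording (well past the slowest post-induction relaxation time at
#' the default rates); pass `plateau_window = "experimental"` for the
#' 6-10 min post-induction window used to quantify recorded potentiation
#' curves.
#'
#' @param x a [replicate_set][run_replicates()].
#' @param baseline_window default `c(0, t_baseline)`.
#' @param plateau_window `c(from, to)` in s, or `"experimental"`.
#' @return object of class `plateau_result`.
#' @export
plateau <- function(x, baseline_window = NULL, plateau_window = NULL) {
  stopifnot(inherits(x, "replicate_set"))
  t_end <- max(x$times)
  t_ind <- x$config$t_baseline
  if (is.null(baseline_window)) baseline_window <- c(0, t_ind)
  if (is.null(plateau_window)) {
    plateau_window <- c(t_end - 300, t_end)
  } else if (identical(plateau_window, "experimental")) {
    plateau_window <- t_ind + c(360, 600)
  }
  bsel <- x$times >= baseline_window[1] & x$times <= baseline_window[2]
  psel <- x$times >= plateau_window[1] & x$times <= plateau_window[2]
  if (!any(bsel) || !any(psel)) {
    stop("empty baseline or plateau window", call. = FALSE)
  }
  baseline_mean <- mean(x$mean[bsel])
  plateau_mean <- mean(x$mean[psel])
  rep_base <- colMeans(x$rep_series[bsel, , drop = FALSE])
  rep_plat <- colMeans(x$rep_series[psel, , drop = FALSE])
  nr <- ncol(x$rep_series)
  sem_pct <- if (nr > 1) {
    stats::sd(100 * rep_plat / rep_base) / sqrt(nr)
  } else {
    NA_real_
  }
  structure(list(baseline_mean = baseline_mean, plateau_mean = plateau_mean,
                 plateau_percent = 100 * plateau_mean / baseline_mean,
                 plateau_percent_sem = sem_pct,
                 baseline_window = baseline_window,
                 plateau_window = plateau_window,
                 baseline_sem = if (nr > 1) stats::sd(rep_base) / sqrt(nr)
                                else NA_real_),
            class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  cat(sprintf("Baseline: %.2f receptors/synapse (window %g-%g s)\n",
              x$baseline_mean, x$baseline_window[1], x$baseline_window[2]))
  cat(sprintf("Plateau : %.2f receptors/synapse = %.1f%% of baseline (window %g-%g s)\n",
              x$plateau_mean, x$plateau_percent, x$plateau_window[1],
              x$plateau_window[2]))
  invisible(x)
}

#' Fold change between two basal counts
#'
#' @param count_a reference count (must be positive).
#' @param count_b comparison count.
#' @return `count_b / count_a`.
#' @export
fold_change_basal <- function(count_a, count_b) {
  if (!is.numeric(count_a) || count_a <= 0) {
    stop("reference count must be positive", call. = FALSE)
  }
  count_b / count_a
}

#' Sweep the binding rate and trace basal content against LTP plateau
#'
#' For each binding rate, runs the unbinding-rate-drop potentiation protocol
#' and records the basal (baseline-window) per-synapse count and the plateau
#' as a percentage of baseline. Synapses with larger `k_on` hold more
#' receptors at rest but, the extra-synaptic reservoir being depleted,
#' respond less to potentiation — the sweep traces that negative
#' relationship.
#'
#' @param config a [sim_config()].
#' @param k_on_values strictly increasing positive binding rates, 1/s.
#'   Default: 20 logarithmically spaced values spanning 0.075-10 /s.
#' @param n_replicates replicates per value.
#' @param base_seed first seed of the first value's replicate block;
#'   consecutive blocks use consecutive seed ranges.
#' @param k_off_base,k_off_potentiated the unbinding step (defaults
#'   0.04 -> 0.004 /s).
#' @param plateau_window passed to [plateau()].
#' @return object of class `sweep_result`: data.frame with `k_on`,
#'   `basal_count`, `plateau_percent` plus closed-form predictions
#'   `predicted_basal` from [enrichment_ratio()] accounting.
#' @export
sweep_kon <- function(config, k_on_values = NULL, n_replicates = 10,
                      base_seed = config$seed, k_off_base = 0.04,
                      k_off_potentiated = 0.004, plateau_window = NULL) {
  if (is.null(k_on_values)) {
    k_on_values <- exp(seq(log(0.075), log(10), length.out = 20))
  }
  stopifnot(all(k_on_values > 0), !is.unsorted(k_on_values, strictly = TRUE))
  rows <- vector("list", length(k_on_values))
  for (i in seq_along(k_on_values)) {
    spec <- protocol("ltp", k_on_base = k_on_values[i],
                     k_off_base = k_off_base,
                     k_off_potentiated = k_off_potentiated)
    rs <- run_replicates(config, spec, n_replicates,
                         base_seed = base_seed + (i - 1) * n_replicates)
    pl <- plateau(rs, plateau_window = plateau_window)
    ratio <- enrichment_ratio(config$p_crossing, config$D_out, config$D_in,
                              k_on_values[i], k_off_base)
    rows[[i]] <- data.frame(k_on = k_on_values[i],
                            basal_count = pl$baseline_mean,
                            plateau_percent = pl$plateau_percent,
                            predicted_basal = predicted_basal_count(config, ratio))
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Binding-rate sweep over %d values (%g-%g /s)\n", nrow(x),
              min(x$k_on), max(x$k_on)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  graphics::plot(x$basal_count, x$plateau_percent, type = "b", pch = 16,
                 xlab = "basal receptors per synapse",
                 ylab = "LTP plateau (% of baseline)", ...)
  invisible(x)
}

#' Map an EPSC amplitude to a receptor count
#'
#' Synaptic currents scale linearly with receptor number; amplitudes
#' expressed as a percentage of the control condition are anchored so that
#' 100% corresponds to `control_count` receptors per synapse.
#'
#' @param epsc_percent EPSC amplitude, % of control (non-negative).
#' @param control_count receptors per synapse in the control condition
#'   (default 33, the experimental anchor).
#' @return receptors per synapse.
#' @examples
#' epsc_to_count(c(100, 200))
#' @export
epsc_to_count <- function(epsc_percent, control_count = 33) {
  if (any(epsc_percent < 0)) {
    stop("EPSC percentage must be non-negative", call. = FALSE)
  }
  epsc_percent / 100 * control_count
}

#' Experimental anchor conditions (for plot overlays only)
#'
#' The experimental conditions against which sweep results are overlaid. The
#' only printed numeric anchor is the 33 receptors/synapse assigned to the
#' control condition's 100% EPSC level; the other conditions are listed by
#' label only (their EPSC values are not packaged). Not used by any
#' simulator-correctness test.
#'
#' @return data.frame with `condition`, `epsc_percent_of_control`,
#'   `receptor_count`.
#' @export
experimental_anchors <- function() {
  data.frame(
    condition = c("control", "optoFGFR1 + light", "Nlgn1-WT rescue",
                  "Nlgn1-Y782A"),
    epsc_percent_of_control = c(100, NA, NA, NA),
    receptor_count = c(33, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}
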