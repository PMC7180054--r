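#' Default synapse layout
#'
#' Places `n` square synapses evenly along the long axis of the membrane
#' rectangle, centred on the short axis. With the default 10 x 2 um region and
#' five synapses this gives centres at x = 1, 3, 5, 7, 9 um, y = 1 um, i.e. a
#' linear density of 0.5 synapse/um.
#'
#' @param n number of synapses.
#' @param region_length,region_width region dimensions (um).
#' @param side side of each square synapse (um), default 0.3.
#' @return data.frame with columns `id`, `center_x`, `center_y`, `side`.
#' @export
default_synapses <- function(n = 5, region_length = 10, region_width = 2,
                             side = 0.3) {
  stopifnot(n >= 1, side > 0)
  spacing <- region_length / n
  data.frame(
    id = seq_len(n),
    center_x = spacing * (seq_len(n) - 0.5),
    center_y = region_width / 2,
    side = side
  )
}

#' Simulation configuration
#'
#' Bundles geometry, diffusion coefficients, barrier behaviour and timing for
#' one simulation. Defaults are the reference parameter set used throughout:
#' a 10 x 2 um dendritic segment holding five 0.3 um synaptic squares and a
#' closed population of 1000 receptors stepped at dt = 0.1 s, with
#' D_out = 0.1, D_in = 0.05 and D_trap = 0.006 um^2/s and a border-crossing
#' probability of 0.5.
#'
#' @param region_length,region_width rectangle dimensions, um.
#' @param synapses data.frame as returned by [default_synapses()]; every
#'   square must lie fully inside the region and squares must not overlap.
#' @param n_receptors closed-system receptor count.
#' @param dt integration time step, s.
#' @param D_out,D_in,D_trap diffusion coefficients (um^2/s) for free receptors
#'   outside synapses, free receptors inside synapses, and scaffold-bound
#'   receptors.
#' @param p_crossing probability that a synapse-border crossing move is
#'   accepted, in `[0, 1]`.
#' @param crossing_mode which border crossings the barrier gates:
#'   `"entry"` (default; consistent with the closed-form enrichment ratio,
#'   see the package vignette), `"exit"`, or `"symmetric"`.
#' @param bound_edge what happens when a bound receptor's proposed move leaves
#'   its synapse square: `"hold"` (default; keep the previous position) or
#'   `"reflect"` (mirror back into the square).
#' @param t_burn_in unrecorded equilibration time before recording, s.
#' @param t_baseline recorded baseline duration, s. Recording time zero is the
#'   start of the baseline; induction protocols switch rates at
#'   `t = t_baseline`.
#' @param t_post recorded post-induction duration, s.
#' @param sample_interval sampling cadence for receptor counts, s.
#' @param seed default RNG seed used when none is supplied to the runners.
#' @return object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config()
#' cfg$n_receptors / nrow(cfg$synapses)  # theoretical per-synapse ceiling
#' @export
sim_config <- function(region_length = 10, region_width = 2,
                       synapses = NULL, n_receptors = 1000, dt = 0.1,
                       D_out = 0.1, D_in = 0.05, D_trap = 0.006,
                       p_crossing = 0.5,
                       crossing_mode = c("entry", "exit", "symmetric"),
                       bound_edge = c("hold", "reflect"),
                       t_burn_in = 300, t_baseline = 300, t_post = 1800,
                       sample_interval = 10, seed = 1L) {
  crossing_mode <- match.arg(crossing_mode)
  bound_edge <- match.arg(bound_edge)
  if (is.null(synapses)) {
    synapses <- default_synapses(5, region_length, region_width)
  }
  cfg <- structure(list(
    region_length = region_length, region_width = region_width,
    synapses = synapses, n_receptors = as.integer(n_receptors), dt = dt,
    D_out = D_out, D_in = D_in, D_trap = D_trap,
    p_crossing = p_crossing, crossing_mode = crossing_mode,
    bound_edge = bound_edge,
    t_burn_in = t_burn_in, t_baseline = t_baseline, t_post = t_post,
    sample_interval = sample_interval, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$region_length) && cfg$region_length > 0,
      "region_length must be positive")
  chk(is.numeric(cfg$region_width) && cfg$region_width > 0,
      "region_width must be positive")
  chk(cfg$n_receptors >= 1, "n_receptors must be >= 1")
  chk(is.numeric(cfg$dt) && cfg$dt > 0, "dt must be positive")
  for (d in c("D_out", "D_in", "D_trap")) {
    chk(is.numeric(cfg[[d]]) && cfg[[d]] >= 0,
        sprintf("%s must be non-negative", d))
  }
  chk(cfg$p_crossing >= 0 && cfg$p_crossing <= 1,
      "p_crossing must lie in [0, 1]")
  for (t in c("t_burn_in", "t_baseline", "t_post")) {
    chk(is.numeric(cfg[[t]]) && cfg[[t]] >= 0,
        sprintf("%s must be non-negative", t))
  }
  chk(cfg$sample_interval > 0, "sample_interval must be positive")
  syn <- cfg$synapses
  chk(is.data.frame(syn) &&
        all(c("id", "center_x", "center_y", "side") %in% names(syn)),
      "synapses must be a data.frame with id, center_x, center_y, side")
  chk(all(syn$side > 0), "synapse side must be positive")
  h <- syn$side / 2
  chk(all(syn$center_x - h >= 0 & syn$center_x + h <= cfg$region_length &
            syn$center_y - h >= 0 & syn$center_y + h <= cfg$region_width),
      "every synapse square must lie fully inside the region")
  if (nrow(syn) > 1) {
    for (i in seq_len(nrow(syn) - 1)) {
      for (j in seq(i + 1, nrow(syn))) {
        overlap <- abs(syn$center_x[i] - syn$center_x[j]) < (h[i] + h[j]) &&
          abs(syn$center_y[i] - syn$center_y[j]) < (h[i] + h[j])
        chk(!overlap, "synapse squares must not overlap")
      }
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  region      : %g x %g um, %d synapses (side %g um)\n",
              x$region_length, x$region_width, nrow(x$synapses),
              x$synapses$side[1]))
  cat(sprintf("  receptors   : %d (closed system), dt = %g s\n",
              x$n_receptors, x$dt))
  cat(sprintf("  diffusion   : D_out %g, D_in %g, D_trap %g um^2/s\n",
              x$D_out, x$D_in, x$D_trap))
  cat(sprintf("  barrier     : p_crossing %g (%s)\n",
              x$p_crossing, x$crossing_mode))
  cat(sprintf("  timing      : burn-in %g s, baseline %g s, post %g s, sampled every %g s\n",
              x$t_burn_in, x$t_baseline, x$t_post, x$sample_interval))
  invisible(x)
}

#' Index of the synapse containing each point
#'
#' @param x,y coordinates (um), recycled to common length.
#' @param synapses synapse table (see [default_synapses()]).
#' @return integer vector of synapse ids; `NA` for points outside every
#'   synapse square. Squares are closed sets; with non-overlapping squares a
#'   boundary point shared by two squares (zero-probability event for
#'   continuous coordinates) is assigned to the lower id.
#' @export
synapse_index <- function(x, y, synapses) {
  out <- rep(NA_integer_, length(x))
  h <- synapses$side / 2
  for (i in rev(seq_len(nrow(synapses)))) {
    inside <- abs(x - synapses$center_x[i]) <= h[i] &
      abs(y - synapses$center_y[i]) <= h[i]
    out[inside] <- synapses$id[i]
  }
  out
}
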