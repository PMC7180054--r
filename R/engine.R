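#' Brownian displacement draws
#'
#' One diffusion step displaces a receptor by `dx = sqrt(2 D dt) n_x`,
#' `dy = sqrt(2 D dt) n_y` with `n_x`, `n_y` independent standard normal
#' deviates, so each axis has mean 0 and standard deviation `sqrt(2 D dt)`.
#' Draws come from the session RNG (seed with [set.seed()]).
#'
#' @param n number of displacement pairs to draw.
#' @param D diffusion coefficient, um^2/s (may be a vector of length `n`).
#' @param dt time step, s.
#' @return two-column matrix `cbind(dx, dy)` in um.
#' @export
draw_displacement <- function(n, D, dt) {
  if (any(D < 0)) stop("D must be non-negative", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  sd <- sqrt(2 * D * dt)
  cbind(dx = sd * stats::rnorm(n), dy = sd * stats::rnorm(n))
}

#' Reflect coordinates into the simulation rectangle
#'
#' The membrane is a closed system: a proposed move past a region edge is
#' mirrored about that edge (repeatedly, should a displacement exceed a full
#' region dimension). Points already inside are unchanged.
#'
#' @param x,y proposed coordinates, um.
#' @param region_length,region_width rectangle dimensions, um.
#' @return list with reflected `x` and `y`, both inside
#'   `[0, region_length] x [0, region_width]`.
#' @export
reflect_into_region <- function(x, y, region_length, region_width) {
  list(x = fold_axis(x, region_length), y = fold_axis(y, region_width))
}

# mirror about 0 and `limit` until inside [0, limit]; closed form via the
# period-2*limit triangle wave so arbitrarily distant points cost O(1)
fold_axis <- function(v, limit) {
  w <- v %% (2 * limit)
  ifelse(w > limit, 2 * limit - w, w)
}

#' Synaptic border-crossing rule
#'
#' A proposed move that changes synapse membership (outside vs inside any
#' synapse square) faces a diffusion barrier: it is accepted with probability
#' `p_crossing`, otherwise the receptor keeps its old position for this step.
#' Moves that do not change membership are always accepted. `crossing_mode`
#' selects which crossings are gated: `"entry"` gates only moves into a
#' synapse (exits are free), `"exit"` the reverse, `"symmetric"` gates both.
#' The entry-only default is the reading consistent with the closed-form
#' enrichment ratio (see [enrichment_ratio()] and the package vignette).
#'
#' @param old_x,old_y current (accepted) positions, um.
#' @param new_x,new_y proposed, already region-reflected positions, um.
#' @param synapses synapse table.
#' @param p_crossing acceptance probability in `[0, 1]`.
#' @param crossing_mode `"entry"`, `"exit"` or `"symmetric"`.
#' @return list with accepted `x`, `y` and logical `crossed` flagging moves
#'   that changed membership and were accepted.
#' @export
apply_crossing_rule <- function(old_x, old_y, new_x, new_y, synapses,
                                p_crossing,
                                crossing_mode = c("entry", "exit", "symmetric")) {
  crossing_mode <- match.arg(crossing_mode)
  if (p_crossing < 0 || p_crossing > 1) {
    stop("p_crossing must lie in [0, 1]", call. = FALSE)
  }
  s_old <- synapse_index(old_x, old_y, synapses)
  s_new <- synapse_index(new_x, new_y, synapses)
  changed <- !((is.na(s_old) & is.na(s_new)) |
                 (!is.na(s_old) & !is.na(s_new) & s_old == s_new))
  gated <- switch(crossing_mode,
    symmetric = changed,
    entry = changed & !is.na(s_new),
    exit = changed & !is.na(s_old)
  )
  accept <- !gated
  if (any(gated)) {
    accept[gated] <- stats::runif(sum(gated)) < p_crossing
  }
  list(x = ifelse(accept, new_x, old_x),
       y = ifelse(accept, new_y, old_y),
       crossed = changed & accept)
}

#' First-order binding/unbinding update
#'
#' Per time step, a free receptor inside a synapse binds the scaffold with
#' probability `min(k_on * dt, 1)`; a bound receptor unbinds with probability
#' `min(k_off * dt, 1)`; a free receptor outside any synapse stays free with
#' certainty. Rates are applied linearly (k * dt), clamped at 1 — they are
#' not exponentiated.
#'
#' @param bound logical vector, `TRUE` for scaffold-bound receptors.
#' @param inside integer vector of containing-synapse ids (`NA` = outside),
#'   as from [synapse_index()].
#' @param k_on,k_off rates, 1/s.
#' @param dt time step, s.
#' @return list with updated logical `bound` and integer `bound_synapse`
#'   (`NA` for free receptors).
#' @export
update_binding_state <- function(bound, inside, k_on, k_off, dt) {
  if (k_on < 0 || k_off < 0) stop("rates must be non-negative", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  p_b <- min(k_on * dt, 1)
  p_u <- min(k_off * dt, 1)
  new_bound <- bound
  bound_syn <- ifelse(bound, inside, NA_integer_)
  can_bind <- !bound & !is.na(inside)
  if (any(can_bind)) {
    binds <- stats::runif(sum(can_bind)) < p_b
    new_bound[can_bind] <- binds
    bound_syn[can_bind][binds] <- inside[can_bind][binds]
  }
  if (any(bound)) {
    unbinds <- stats::runif(sum(bound)) < p_u
    new_bound[bound][unbinds] <- FALSE
    bound_syn[bound][unbinds] <- NA_integer_
  }
  list(bound = new_bound, bound_synapse = bound_syn)
}

#' Initial receptor ensemble
#'
#' Receptors start free, uniformly distributed over the whole rectangle
#' (synapse interiors included).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `x`, `y`, `bound`, `bound_synapse`.
#' @export
init_ensemble <- function(config) {
  n <- config$n_receptors
  data.frame(
    x = stats::runif(n, 0, config$region_length),
    y = stats::runif(n, 0, config$region_width),
    bound = rep(FALSE, n),
    bound_synapse = rep(NA_integer_, n)
  )
}

#' Advance the ensemble by one time step (reference implementation)
#'
#' One `dt` update, in the documented order: (1) binding/unbinding using the
#' position at the start of the step; (2) Brownian displacement with the
#' state-dependent coefficient (bound: `D_trap`; free inside a synapse:
#' `D_in`; free outside: `D_out`); (3) mirror reflection at the region edges;
#' (4) the border-crossing rule for free receptors; (5) confinement of bound
#' receptors, whose proposed move outside their synapse square is rejected
#' (position held) or mirrored back, per `config$bound_edge`.
#'
#' This vectorized R stepper defines the update semantics; [run_simulation()]
#' uses a compiled implementation of the same cycle.
#'
#' @param ensemble data.frame as from [init_ensemble()].
#' @param config a [sim_config()].
#' @param k_on,k_off rates (1/s) in force during this step.
#' @return updated ensemble.
#' @export
sim_step <- function(ensemble, config, k_on, k_off) {
  n <- nrow(ensemble)
  if (n != config$n_receptors) {
    stop("ensemble size does not match n_receptors (closed system violated)",
         call. = FALSE)
  }
  syn <- config$synapses
  inside <- synapse_index(ensemble$x, ensemble$y, syn)
  if (any(ensemble$bound & is.na(inside))) {
    stop("bound receptor found outside any synapse square", call. = FALSE)
  }

  st <- update_binding_state(ensemble$bound, inside, k_on, k_off, config$dt)

  D <- ifelse(st$bound, config$D_trap,
              ifelse(is.na(inside), config$D_out, config$D_in))
  dis <- draw_displacement(n, D, config$dt)
  prop <- reflect_into_region(ensemble$x + dis[, 1], ensemble$y + dis[, 2],
                              config$region_length, config$region_width)

  x_new <- ensemble$x
  y_new <- ensemble$y

  free <- !st$bound
  if (any(free)) {
    acc <- apply_crossing_rule(ensemble$x[free], ensemble$y[free],
                               prop$x[free], prop$y[free], syn,
                               config$p_crossing, config$crossing_mode)
    x_new[free] <- acc$x
    y_new[free] <- acc$y
  }
  if (any(st$bound)) {
    b <- which(st$bound)
    row <- match(st$bound_synapse[b], syn$id)
    h <- syn$side[row] / 2
    cx <- syn$center_x[row]
    cy <- syn$center_y[row]
    px <- prop$x[b]
    py <- prop$y[b]
    stays <- abs(px - cx) <= h & abs(py - cy) <= h
    if (config$bound_edge == "hold") {
      x_new[b] <- ifelse(stays, px, ensemble$x[b])
      y_new[b] <- ifelse(stays, py, ensemble$y[b])
    } else {
      x_new[b] <- cx + fold_axis(px - cx + h, 2 * h) - h
      y_new[b] <- cy + fold_axis(py - cy + h, 2 * h) - h
    }
  }
  data.frame(x = x_new, y = y_new, bound = st$bound,
             bound_synapse = st$bound_synapse)
}
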