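#' Piecewise-constant binding/unbinding rate schedule
#'
#' Kinetic rates are piecewise-constant, right-continuous functions of
#' simulation time (recording time zero = start of baseline; burn-in occupies
#' negative times). Interval `i` spans `[breakpoints[i], breakpoints[i+1])`;
#' the first breakpoint is normally `-Inf` so the schedule covers burn-in.
#'
#' @param breakpoints strictly increasing numeric vector of interval start
#'   times (s).
#' @param k_on,k_off binding/unbinding rates (1/s), one value per interval.
#' @return object of class `kinetic_schedule`.
#' @export
kinetic_schedule <- function(breakpoints, k_on, k_off) {
  stopifnot(length(breakpoints) == length(k_on),
            length(breakpoints) == length(k_off))
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (any(k_on < 0) || any(k_off < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, k_on = k_on, k_off = k_off),
            class = "kinetic_schedule")
}

#' Constant-rate schedule
#' @param k_on,k_off rates (1/s).
#' @rdname kinetic_schedule
#' @export
constant_schedule <- function(k_on, k_off) {
  kinetic_schedule(-Inf, k_on, k_off)
}

#' Evaluate a schedule at given times
#'
#' @param schedule a [kinetic_schedule()].
#' @param t numeric vector of times (s).
#' @return list with numeric vectors `k_on` and `k_off`.
#' @export
rate_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$breakpoints)
  if (any(idx == 0)) {
    stop("schedule does not cover the requested times", call. = FALSE)
  }
  list(k_on = schedule$k_on[idx], k_off = schedule$k_off[idx])
}

#' @export
print.kinetic_schedule <- function(x, ...) {
  cat("Kinetic schedule (right-continuous, piecewise constant)\n")
  for (i in seq_along(x$breakpoints)) {
    to <- if (i < length(x$breakpoints)) x$breakpoints[i + 1] else Inf
    cat(sprintf("  t in [%g, %g): k_on = %g /s, k_off = %g /s\n",
                x$breakpoints[i], to, x$k_on[i], x$k_off[i]))
  }
  invisible(x)
}

PROTOCOL_NAMES <- c("basal", "ltp", "phospho_basal", "phospho_ltp",
                    "ko_ltp", "kon_step_ltp")

#' Experiment protocol specifications
#'
#' Builds the kinetic protocols used in the plasticity experiments:
#' \describe{
#'   \item{basal}{constant rates (defaults k_on = 1/s, k_off = 0.04/s); the
#'     control steady state.}
#'   \item{ltp}{long-term potentiation mimicked as a step decrease of the
#'     unbinding rate (default 0.04 to 0.004/s) at induction, binding rate
#'     unchanged.}
#'   \item{phospho_basal}{scaffold-assembly phosphorylation mimicked as an
#'     elevated binding rate from the start (default k_on = 3/s), no
#'     induction step.}
#'   \item{phospho_ltp}{the ltp protocol run on top of the elevated binding
#'     rate (k_on = 3/s throughout, k_off 0.04 to 0.004/s).}
#'   \item{ko_ltp}{the knockout variant: k_on = 1/s with a weaker unbinding
#'     drop, 0.04 to 0.008/s.}
#'   \item{kon_step_ltp}{the rejected alternative potentiation mechanism: the
#'     binding rate steps up at induction (default 1 to 10/s, chosen so that
#'     the post-induction k_on/k_off equals the ltp protocol's, giving a
#'     matched plateau) with k_off constant.}
#' }
#'
#' @param name protocol name: `"basal"`, `"ltp"`, `"phospho_basal"`,
#'   `"phospho_ltp"`, `"ko_ltp"` or `"kon_step_ltp"`.
#' @param k_on_base,k_off_base pre-induction rates (1/s). `k_on_base`
#'   defaults to 3 for the phospho variants, 1 otherwise.
#' @param k_off_potentiated post-induction unbinding rate for the LTP
#'   variants; must be below `k_off_base`.
#' @param k_on_potentiated post-induction binding rate for `kon_step_ltp`;
#'   must exceed `k_on_base`.
#' @param t_induction induction time (s) relative to recording start; `NULL`
#'   means "end of the baseline window" and is resolved against the
#'   configuration by [make_schedule()].
#' @return object of class `protocol_spec`.
#' @export
protocol <- function(name, k_on_base = NULL, k_off_base = 0.04,
                     k_off_potentiated = NULL, k_on_potentiated = NULL,
                     t_induction = NULL) {
  name <- match.arg(name, PROTOCOL_NAMES)
  phospho <- name %in% c("phospho_basal", "phospho_ltp")
  if (is.null(k_on_base)) k_on_base <- if (phospho) 3 else 1
  has_koff_drop <- name %in% c("ltp", "phospho_ltp", "ko_ltp")
  if (has_koff_drop && is.null(k_off_potentiated)) {
    k_off_potentiated <- if (name == "ko_ltp") 0.008 else 0.004
  }
  if (name == "kon_step_ltp" && is.null(k_on_potentiated)) {
    k_on_potentiated <- 10
  }
  if (has_koff_drop) {
    if (!is.numeric(k_off_potentiated) || k_off_potentiated >= k_off_base) {
      stop("k_off_potentiated must be smaller than k_off_base for LTP variants",
           call. = FALSE)
    }
  }
  if (name == "kon_step_ltp") {
    if (!is.numeric(k_on_potentiated) || k_on_potentiated <= k_on_base) {
      stop("k_on_potentiated must exceed k_on_base for kon_step_ltp",
           call. = FALSE)
    }
  }
  structure(list(name = name, k_on_base = k_on_base, k_off_base = k_off_base,
                 k_off_potentiated = k_off_potentiated,
                 k_on_potentiated = k_on_potentiated,
                 t_induction = t_induction),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Protocol '%s': k_on %g /s, k_off %g /s", x$name,
              x$k_on_base, x$k_off_base))
  if (!is.null(x$k_off_potentiated)) {
    cat(sprintf("; k_off -> %g /s at induction", x$k_off_potentiated))
  }
  if (!is.null(x$k_on_potentiated)) {
    cat(sprintf("; k_on -> %g /s at induction", x$k_on_potentiated))
  }
  cat("\n")
  invisible(x)
}

#' Build the kinetic schedule for a protocol
#'
#' Resolves a [protocol()] specification against a configuration: induction
#' (when the protocol has one) happens at the end of the recorded baseline
#' window unless the spec carries an explicit `t_induction`.
#'
#' @param spec a [protocol_spec][protocol()].
#' @param config a [sim_config()].
#' @return a [kinetic_schedule()] spanning burn-in, baseline and
#'   post-induction phases.
#' @export
make_schedule <- function(spec, config) {
  stopifnot(inherits(spec, "protocol_spec"), inherits(config, "sim_config"))
  t_ind <- if (is.null(spec$t_induction)) config$t_baseline else spec$t_induction
  switch(spec$name,
    basal = ,
    phospho_basal = constant_schedule(spec$k_on_base, spec$k_off_base),
    ltp = ,
    phospho_ltp = ,
    ko_ltp = kinetic_schedule(
      breakpoints = c(-Inf, t_ind),
      k_on = rep(spec$k_on_base, 2),
      k_off = c(spec$k_off_base, spec$k_off_potentiated)
    ),
    kon_step_ltp = kinetic_schedule(
      breakpoints = c(-Inf, t_ind),
      k_on = c(spec$k_on_base, spec$k_on_potentiated),
      k_off = rep(spec$k_off_base, 2)
    )
  )
}
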