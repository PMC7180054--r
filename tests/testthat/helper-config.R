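# Reduced problem sizes for fast unit tests; full-scale runs live in
# test-acceptance.R. Defaults otherwise identical to sim_config().
small_config <- function(n_receptors = 200, t_burn_in = 60, t_baseline = 60,
                         t_post = 120, sample_interval = 10, ...) {
  sim_config(n_receptors = n_receptors, t_burn_in = t_burn_in,
             t_baseline = t_baseline, t_post = t_post,
             sample_interval = sample_interval, ...)
}

# baseline-window per-replicate means of the per-synapse count
baseline_rep_means <- function(rs) {
  sel <- rs$times <= rs$config$t_baseline
  colMeans(rs$rep_series[sel, , drop = FALSE])
}
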