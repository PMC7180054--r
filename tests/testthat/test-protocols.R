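test_that("schedules are deterministic functions of their specs", {
  cfg <- sim_config()
  s1 <- make_schedule(protocol("ltp"), cfg)
  s2 <- make_schedule(protocol("ltp"), cfg)
  expect_identical(s1, s2)
})

test_that("protocol schedules carry the documented rate steps", {
  cfg <- sim_config()

  basal <- make_schedule(protocol("basal"), cfg)
  expect_length(basal$breakpoints, 1)  # constant, no induction breakpoint
  expect_equal(rate_at(basal, c(-300, 0, 2000)),
               list(k_on = c(1, 1, 1), k_off = c(0.04, 0.04, 0.04)))

  ltp <- make_schedule(protocol("ltp"), cfg)
  r <- rate_at(ltp, c(299.9, 300, 1500))
  expect_equal(r$k_off, c(0.04, 0.004, 0.004))  # right-continuous step
  expect_equal(r$k_on, c(1, 1, 1))

  ko <- make_schedule(protocol("ko_ltp"), cfg)
  expect_equal(rate_at(ko, 400)$k_off, 0.008)
  expect_equal(rate_at(ko, 400)$k_on, 1)

  ph <- make_schedule(protocol("phospho_ltp"), cfg)
  expect_equal(rate_at(ph, c(0, 400))$k_on, c(3, 3))
  expect_equal(rate_at(ph, c(0, 400))$k_off, c(0.04, 0.004))

  ks <- make_schedule(protocol("kon_step_ltp"), cfg)
  expect_equal(rate_at(ks, c(0, 400))$k_on, c(1, 10))
  expect_equal(rate_at(ks, c(0, 400))$k_off, c(0.04, 0.04))
})

test_that("ill-formed protocol variants are rejected", {
  expect_error(protocol("nonsense"))
  expect_error(protocol("ltp", k_off_potentiated = 0.05),
               "smaller than k_off_base")
  expect_error(protocol("kon_step_ltp", k_on_potentiated = 0.5),
               "exceed k_on_base")
})

test_that("a schedule must span the whole simulated interval", {
  cfg <- small_config()
  short <- kinetic_schedule(breakpoints = 0, k_on = 1, k_off = 0.04)
  expect_error(run_simulation(cfg, short), "span")
})

test_that("replicate summaries average the member series; SEM needs n > 1", {
  cfg <- small_config()
  one <- run_replicates(cfg, protocol("basal"), n_replicates = 1,
                        base_seed = 4)
  single <- run_simulation(cfg, protocol("basal"), seed = 4)
  expect_equal(one$mean, rowMeans(single$total))
  expect_true(all(is.na(one$sem)))

  rs <- run_replicates(cfg, protocol("basal"), n_replicates = 3,
                       base_seed = 4)
  expect_identical(rs$seeds, 4:6)
  expect_equal(rs$mean, rowMeans(rs$rep_series))
  expect_equal(rs$sem, apply(rs$rep_series, 1, sd) / sqrt(3))
  # first member reproduces the standalone run with the same seed
  expect_equal(rs$rep_series[, 1], rowMeans(single$total))
})

test_that("replicate sets with the same base seed are identical", {
  cfg <- small_config()
  a <- run_replicates(cfg, protocol("ltp"), n_replicates = 2, base_seed = 21)
  b <- run_replicates(cfg, protocol("ltp"), n_replicates = 2, base_seed = 21)
  expect_identical(a$rep_series, b$rep_series)
  expect_identical(a$mean, b$mean)
})

test_that("potentiation raises the synaptic count after induction", {
  cfg <- small_config(n_receptors = 500)
  rs <- run_replicates(cfg, protocol("ltp"), n_replicates = 4, base_seed = 1)
  t_ind <- cfg$t_baseline
  # one-sided trend over the first minutes post-induction, on replicate means
  post <- rs$times > t_ind
  early <- rs$times > t_ind & rs$times <= t_ind + 100
  base <- rs$times <= t_ind
  expect_gt(mean(rs$mean[early]), mean(rs$mean[base]))
  fit <- lm(y ~ t, data.frame(t = rs$times[early], y = rs$mean[early]))
  expect_gt(coef(fit)["t"], 0)
  # and the late plateau exceeds the early rise (non-decreasing to plateau)
  late <- rs$times >= max(rs$times) - 50
  expect_gt(mean(rs$mean[late]), mean(rs$mean[early]))
})
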