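test_that("the closed-form enrichment ratio evaluates as printed", {
  expect_equal(enrichment_ratio(0.5, 0.1, 0.05, 1, 0.04), 26)
  expect_equal(enrichment_ratio(0.5, 0.1, 0.05, 0, 0.04), 1)  # no binding
  expect_equal(enrichment_ratio(0.5, 0.1, 0.05, 0, 0), 1)
  expect_equal(enrichment_ratio(1, 0.07, 0.07, 0, 1), 1)      # identity case
  expect_warning(r <- enrichment_ratio(0.5, 0.1, 0.05, 1, 0), "unbounded")
  expect_identical(r, Inf)
})

test_that("conservation accounting converts a ratio into a per-synapse count", {
  cfg <- sim_config()
  expect_equal(predicted_basal_count(cfg, 1), 1000 * 0.09 / 20)  # 4.5
  expect_equal(predicted_basal_count(cfg, 0), 0)
  # the default closed-form ratio implies about 75 receptors per synapse
  r <- enrichment_ratio(0.5, 0.1, 0.05, 1, 0.04)
  expect_equal(predicted_basal_count(cfg, r),
               26 * 1000 / (19.55 + 26 * 0.45) * 0.09)
  expect_equal(predicted_basal_count(cfg, r), 74.88, tolerance = 1e-4)
  # saturation: an infinite ratio captures the whole population
  expect_equal(predicted_basal_count(cfg, Inf), 200)
})

test_that("baseline normalization is scale-invariant and anchored at 100%", {
  t <- seq(0, 100, 10)
  v <- c(rep(10, 5), rep(20, 6))
  n1 <- percent_of_baseline(v, t, c(0, 40))
  expect_equal(n1[1:5], rep(100, 5))
  expect_equal(n1[6:11], rep(200, 6))
  expect_equal(percent_of_baseline(7 * v, t, c(0, 40)), n1)
  expect_equal(percent_of_baseline(rep(3, 11), t, c(0, 40)), rep(100, 11))
  expect_error(percent_of_baseline(rep(0, 11), t, c(0, 40)), "zero")
  expect_error(percent_of_baseline(v, t, c(500, 600)), "no samples")
})

test_that("plateau_level averages the normalized series over its window", {
  t <- seq(0, 100, 10)
  expect_equal(plateau_level(rep(100, 11), t, c(50, 100)), 100)
  v <- c(rep(100, 6), rep(250, 5))
  expect_equal(plateau_level(v, t, c(60, 100)), 250)
  expect_error(plateau_level(v, t, c(500, 600)), "no samples")
})

test_that("fold change requires a positive reference", {
  expect_equal(fold_change_basal(30, 30), 1)
  expect_equal(fold_change_basal(30, 60), 2)
  expect_error(fold_change_basal(0, 60), "positive")
})

test_that("EPSC amplitudes map linearly onto receptor counts", {
  expect_equal(epsc_to_count(100), 33)
  expect_equal(epsc_to_count(0), 0)
  expect_equal(epsc_to_count(200), 66)
  expect_error(epsc_to_count(-5), "non-negative")
  a <- experimental_anchors()
  expect_equal(a$receptor_count[a$condition == "control"], 33)
})

test_that("a no-induction protocol plateaus at its own baseline", {
  cfg <- small_config()
  rs <- run_replicates(cfg, protocol("basal"), n_replicates = 4,
                       base_seed = 31)
  pl <- plateau(rs, plateau_window = c(100, 180))
  sem_pct <- 100 * sd(baseline_rep_means(rs)) / sqrt(4) / pl$baseline_mean
  expect_equal(pl$plateau_percent, 100, tolerance = 3 * sem_pct / 100 + 0.05)
})

test_that("simulated basal content matches the closed form when the barrier and diffusivity contrast are off", {
  # with p_crossing = 1 and D_in = D_out the discrete scheme has no border
  # artifact, so the closed-form ratio (26) and conservation accounting
  # predict the simulated basal count directly
  cfg <- sim_config(p_crossing = 1, D_in = 0.1)
  rs <- run_replicates(cfg, protocol("basal"), n_replicates = 5,
                       base_seed = 3)
  rep_means <- baseline_rep_means(rs)
  pred <- predicted_basal_count(cfg, enrichment_ratio(1, 0.1, 0.1, 1, 0.04))
  se <- sd(rep_means) / sqrt(5)
  expect_lt(abs(mean(rep_means) - pred), 3 * se)
})
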