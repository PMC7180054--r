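test_that("the ensemble is conserved and contained at every sample", {
  cfg <- small_config()
  sim <- run_simulation(cfg, protocol("basal"), seed = 1)
  expect_true(all(rowSums(sim$total) + sim$extra == cfg$n_receptors))
  expect_true(all(sim$bound >= 0))
  expect_true(all(sim$total >= sim$bound))
  ens <- sim$ensemble
  expect_equal(nrow(ens), cfg$n_receptors)
  expect_true(all(ens$x >= 0 & ens$x <= cfg$region_length &
                    ens$y >= 0 & ens$y <= cfg$region_width))
  # bound receptors sit inside their own synapse square
  b <- ens[ens$bound, ]
  if (nrow(b) > 0) {
    expect_identical(synapse_index(b$x, b$y, cfg$synapses), b$bound_synapse)
  }
})

test_that("identical seed and configuration give identical trajectories", {
  cfg <- small_config()
  a <- run_simulation(cfg, protocol("ltp"), seed = 99)
  b <- run_simulation(cfg, protocol("ltp"), seed = 99)
  expect_identical(a$total, b$total)
  expect_identical(a$bound, b$bound)
  expect_identical(a$ensemble, b$ensemble)
  c <- run_simulation(cfg, protocol("ltp"), seed = 100)
  expect_false(identical(a$total, c$total))
})

test_that("k_on = 0 leaves every receptor free", {
  cfg <- small_config()
  sim <- run_simulation(cfg, constant_schedule(0, 0.04), seed = 2)
  expect_true(all(sim$bound == 0))
  expect_false(any(sim$ensemble$bound))
})

test_that("with no binding, no barrier and equal diffusivity the spatial density is uniform", {
  # pooled end-of-run snapshots from independent runs: if the free-diffusion
  # dynamics preserve the uniform initial law, bin counts are multinomial
  cfg <- sim_config(n_receptors = 1000, t_burn_in = 0, t_baseline = 50,
                    t_post = 50, p_crossing = 1, D_in = 0.1)
  pos <- do.call(rbind, lapply(1:10, function(s) {
    run_simulation(cfg, constant_schedule(0, 0.04), seed = s)$ensemble[, c("x", "y")]
  }))
  ix <- pmin(floor(pos$x / 0.5), 19)
  iy <- pmin(floor(pos$y / 0.5), 3)
  counts <- tabulate(1 + ix + 20 * iy, nbins = 80)
  p <- chisq.test(counts, p = rep(1 / 80, 80))$p.value
  expect_gt(p, 0.001)
})

test_that("the R reference stepper obeys the same invariants as the engine", {
  cfg <- small_config(n_receptors = 100)
  set.seed(5)
  ens <- init_ensemble(cfg)
  for (i in 1:200) {
    ens <- sim_step(ens, cfg, k_on = 1, k_off = 0.04)
  }
  expect_equal(nrow(ens), 100)
  expect_true(all(ens$x >= 0 & ens$x <= 10 & ens$y >= 0 & ens$y <= 2))
  b <- ens[ens$bound, ]
  expect_identical(synapse_index(b$x, b$y, cfg$synapses), b$bound_synapse)
  expect_gt(nrow(b), 0)  # trapping does happen at the default rates
})

test_that("R stepper and compiled engine agree on the basal steady state", {
  # statistical cross-check: same physics, independent implementations
  cfg <- sim_config(n_receptors = 300, t_burn_in = 150, t_baseline = 150,
                    t_post = 0)
  eng <- sapply(1:4, function(s) {
    sim <- run_simulation(cfg, protocol("basal"), seed = s)
    mean(rowMeans(sim$total))
  })
  rsteps <- round((cfg$t_burn_in + cfg$t_baseline) / cfg$dt)
  burn <- round(cfg$t_burn_in / cfg$dt)
  rref <- sapply(5:8, function(s) {
    set.seed(s)
    ens <- init_ensemble(cfg)
    acc <- numeric(0)
    for (i in seq_len(rsteps)) {
      ens <- sim_step(ens, cfg, 1, 0.04)
      if (i > burn && i %% 100 == 0) {
        acc <- c(acc, mean(table(factor(
          synapse_index(ens$x, ens$y, cfg$synapses), levels = 1:5))))
      }
    }
    mean(acc)
  })
  se <- sqrt(var(eng) / 4 + var(rref) / 4)
  expect_lt(abs(mean(eng) - mean(rref)), 4 * se)
})

test_that("occupancy grids tile the region and average the receptor count", {
  cfg <- small_config()
  sim <- run_simulation(cfg, protocol("basal"), seed = 3,
                        record_occupancy = TRUE, occupancy_bin = 0.25)
  g <- sim$occupancy$grid
  expect_equal(dim(g), c(2 / 0.25, 10 / 0.25))
  expect_true(all(g >= 0))
  # time-averaged total over all bins equals the closed receptor count
  expect_equal(sum(g), cfg$n_receptors, tolerance = 1e-12)
  expect_error(
    run_simulation(cfg, protocol("basal"), record_occupancy = TRUE,
                   occupancy_bin = 0.3),
    "tile"
  )
})
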