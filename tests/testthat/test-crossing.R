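# proposals hopping between a point inside synapse 3 and a point outside it
membership_proposals <- function(n, syn) {
  inside_x <- syn$center_x[3]
  outside_x <- syn$center_x[3] + 0.5
  data.frame(old_x = rep(inside_x, n), old_y = 1,
             new_x = rep(outside_x, n), new_y = 1)
}

test_that("p_crossing = 1 removes the barrier entirely", {
  syn <- default_synapses()
  pr <- membership_proposals(200, syn)
  set.seed(1)
  acc <- apply_crossing_rule(pr$old_x, pr$old_y, pr$new_x, pr$new_y, syn,
                             p_crossing = 1, crossing_mode = "symmetric")
  expect_true(all(acc$x == pr$new_x))
  expect_true(all(acc$crossed))
})

test_that("p_crossing = 0 makes synapses absorbing compartments", {
  syn <- default_synapses()
  pr <- membership_proposals(200, syn)
  set.seed(1)
  acc <- apply_crossing_rule(pr$old_x, pr$old_y, pr$new_x, pr$new_y, syn,
                             p_crossing = 0, crossing_mode = "symmetric")
  expect_true(all(acc$x == pr$old_x))
  expect_false(any(acc$crossed))
  # entering is equally blocked
  acc_in <- apply_crossing_rule(pr$new_x, pr$new_y, pr$old_x, pr$old_y, syn,
                                p_crossing = 0, crossing_mode = "symmetric")
  expect_true(all(acc_in$x == pr$new_x))
})

test_that("membership-changing moves are accepted at the Bernoulli rate", {
  syn <- default_synapses()
  n <- 1e5
  pr <- membership_proposals(n, syn)
  set.seed(2)
  acc <- apply_crossing_rule(pr$old_x, pr$old_y, pr$new_x, pr$new_y, syn,
                             p_crossing = 0.5, crossing_mode = "symmetric")
  frac <- mean(acc$crossed)
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("moves that keep membership are never gated", {
  syn <- default_synapses()
  set.seed(3)
  # within the same synapse, and fully extra-synaptic moves
  acc1 <- apply_crossing_rule(5, 1, 5.1, 1.05, syn, p_crossing = 0)
  expect_equal(c(acc1$x, acc1$y), c(5.1, 1.05))
  acc2 <- apply_crossing_rule(2, 0.2, 2.3, 0.3, syn, p_crossing = 0)
  expect_equal(acc2$x, 2.3)
})

test_that("entry-only mode gates entries but leaves exits free", {
  syn <- default_synapses()
  n <- 500
  pr <- membership_proposals(n, syn)
  set.seed(4)
  # exit attempts: always accepted
  out <- apply_crossing_rule(pr$old_x, pr$old_y, pr$new_x, pr$new_y, syn,
                             p_crossing = 0, crossing_mode = "entry")
  expect_true(all(out$x == pr$new_x))
  # entry attempts: all rejected at p = 0
  inn <- apply_crossing_rule(pr$new_x, pr$new_y, pr$old_x, pr$old_y, syn,
                             p_crossing = 0, crossing_mode = "entry")
  expect_true(all(inn$x == pr$new_x))
})
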