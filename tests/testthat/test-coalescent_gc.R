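test_that("expected segregating sites follows the Watterson formula", {
  p <- sim_params(theta = 1e-3, genome_length = 10000, sample_size = 2)
  expect_equal(expected_segregating_sites(p), 10)
  p4 <- sim_params(theta = 1e-3, genome_length = 10000, sample_size = 4)
  expect_equal(expected_segregating_sites(p4), 10 * (1 + 1 / 2 + 1 / 3))
  p0 <- sim_params(theta = 0, genome_length = 10000, sample_size = 5)
  expect_equal(expected_segregating_sites(p0), 0)
})

test_that("degenerate inputs behave: theta = 0 gives no variation", {
  set.seed(1)
  r <- simulate_coalescent_gc(sim_params(theta = 0, rho = 1e-3,
                                         tract_length = 100,
                                         genome_length = 5000,
                                         sample_size = 6))
  expect_length(r$alignment$variant_positions, 0)
  expect_identical(length(unique(r$alignment$sequences)), 1L)
})

test_that("identical seed and parameters give bit-identical output", {
  p <- sim_params(theta = 2e-3, rho = 1e-4, tract_length = 500,
                  genome_length = 10000, sample_size = 8, seed = 77)
  r1 <- simulate_coalescent_gc(p, emit = "alignment")
  r2 <- simulate_coalescent_gc(p, emit = "alignment")
  expect_identical(r1$alignment$sequences, r2$alignment$sequences)
  expect_identical(r1$n_recomb_events, r2$n_recomb_events)
})

test_that("simulator is calibrated against the neutral expectation", {
  set.seed(202)
  p <- sim_params(theta = 1e-3, rho = 0, genome_length = 10000,
                  sample_size = 5)
  S <- replicate(400, length(
    simulate_coalescent_gc(p, emit = "sites")$alignment$variant_positions))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected_segregating_sites(p)), 3 * se)
})

test_that("rho = 0 yields a single genealogy: no recombination events and
           zero four-gamete failures, always", {
  set.seed(303)
  for (i in 1:60) {
    r <- simulate_coalescent_gc(sim_params(theta = 3e-3, rho = 0,
                                           genome_length = 8000,
                                           sample_size = 10), emit = "sites")
    expect_identical(r$n_recomb_events, 0L)
    f <- four_gamete_profile(r$alignment)
    expect_identical(sum(f$n_failing), 0L)
  }
})

test_that("mean segregating sites is invariant to rho (marginal trees are
           unaffected by gene conversion)", {
  set.seed(404)
  p_hi <- sim_params(theta = 2e-3, rho = 1e-3, tract_length = 1000,
                     genome_length = 10000, sample_size = 10)
  S <- replicate(200, length(
    simulate_coalescent_gc(p_hi, emit = "sites")$alignment$variant_positions))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected_segregating_sites(p_hi)), 3 * se)
})

test_that("four-gamete failure proportion increases with rho", {
  set.seed(505)
  f4 <- function(rho) mean(replicate(120, f4_failure_prop(
    sim_params(theta = 2e-3, rho = rho, tract_length = 1000,
               genome_length = 10000, sample_size = 10))), na.rm = TRUE)
  lo <- f4(1e-5); mid <- f4(1e-4); hi <- f4(1e-3)
  expect_lt(lo, mid)
  expect_lt(mid, hi)
})

test_that("parameter validation and the event budget guard fire", {
  expect_error(sim_params(theta = -1), "theta")
  expect_error(sim_params(theta = 1e-3, sample_size = 1), "sample_size")
  expect_error(sim_params(theta = 5e-2, genome_length = 100), "exceed")
  set.seed(9)
  expect_error(simulate_coalescent_gc(
    sim_params(theta = 1e-3, rho = 1e-2, tract_length = 1e5,
               genome_length = 20000, sample_size = 10),
    event_budget = 10), "event budget")
})
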