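test_that("closed-form equilibrium variance expectations", {
  expect_equal(hoc_expectation(3e-3, 1), 0.012)
  expect_equal(hoc_expectation(0, 50), 0)
  expect_equal(hoc_expectation(3e-3, 50), 0.6)
  expect_equal(stochastic_hoc_expectation(3e-3, 1, 10000, 0.05),
               0.012 / 1.04)
  expect_equal(stochastic_hoc_expectation(3e-3, 50, 10000, 0.9),
               0.6 / (1 + 50 / 8100))
  # converges to the deterministic value for large mutational variance
  expect_equal(stochastic_hoc_expectation(3e-3, 5, 1000, 1e6),
               hoc_expectation(3e-3, 5), tolerance = 1e-6)
})

test_that("time to optimum uses the 99% criterion in N_anc units", {
  traj <- data.frame(generation = 1:10,
                     mean_trait = c(rep(0, 6), 10, 10, 10, 10))
  expect_equal(time_to_optimum(traj, 10, 1000), 0.007)
  never <- data.frame(generation = 1:10, mean_trait = rep(9.89, 10))
  expect_true(is.na(time_to_optimum(never, 10, 1000)))
  # a mean of exactly 9.9 counts as reaching 99% of 10
  edge <- data.frame(generation = 1:3, mean_trait = c(1, 9.9, 10))
  expect_equal(time_to_optimum(edge, 10, 100), 0.02)
})

test_that("adaptation rate is distance in z-scores over generations", {
  traj <- data.frame(generation = 1:100,
                     mean_trait = c(rep(0, 99), 10))
  expect_equal(adaptation_rate(traj, V_G0 = 1, z_opt_new = 10), 0.1)
  # doubling the time halves the rate
  traj2 <- data.frame(generation = 1:200,
                      mean_trait = c(rep(0, 199), 10))
  expect_equal(adaptation_rate(traj2, 1, 10),
               adaptation_rate(traj, 1, 10) / 2)
  # invariant to shifting optimum and start by the same constant
  traj3 <- data.frame(generation = 1:100,
                      mean_trait = c(rep(5, 99), 15))
  expect_equal(adaptation_rate(traj3, 1, 15, z_initial = 5),
               adaptation_rate(traj, 1, 10))
  expect_error(adaptation_rate(traj, 0, 10), "positive")
})

test_that("site frequency spectrum bins counts with a 1/i reference", {
  s <- sfs(c(0.5), n_bins = 20, two_N = 100)
  expect_identical(sum(s$count), 1L)
  expect_identical(s$count[s$bin_lo == 0.5], 1L)
  # neutral reference sums to the observed number of sites
  set.seed(40)
  fr <- runif(200)
  s2 <- sfs(fr, n_bins = 10, two_N = 200)
  expect_equal(sum(s2$neutral_expected), 200)
  expect_identical(sum(s2$count), 200L)
  # reference is decreasing in frequency (excess of rares)
  expect_true(all(diff(s2$neutral_expected) < 0))
  # empty input
  s3 <- sfs(numeric(0), n_bins = 5, two_N = 10)
  expect_true(all(s3$count == 0))
})

test_that("fixation and segregating-site descriptors partition by sign", {
  fx <- fixation_stats(data.frame(effect = c(0.1, -0.02, 0.3)))
  expect_identical(fx$n_fixations, 3L)
  expect_equal(fx$mean_effect_pos, 0.2)
  expect_equal(fx$mean_effect_neg, -0.02)
  # no negatives: mean is missing, not zero
  fx2 <- fixation_stats(data.frame(effect = c(0.1, 0.3)))
  expect_true(is.na(fx2$mean_effect_neg))

  seg <- segregating_stats(data.frame(effect = c(0.2, -0.2, 0.4, -0.4),
                                      frequency = c(0.1, 0.3, 0.5, 0.7)))
  expect_equal(seg$prop_negative, 0.5)
  expect_equal(seg$mean_freq_neg, 0.5)
  expect_equal(seg$mean_effect_pos, 0.3)
  all_pos <- segregating_stats(data.frame(effect = c(0.1, 0.2),
                                          frequency = c(0.1, 0.2)))
  expect_equal(all_pos$prop_negative, 0)
  expect_true(is.na(all_pos$mean_freq_neg))
})

test_that("replicate summaries aggregate by parameter set", {
  set.seed(41)
  d <- demography_model(100)
  b <- run_burn_in(trait_params(0.9, 50), d)
  V_G0 <- mean(tail(b$trajectory$var_G, 200))
  null <- simulate_neutral_sojourns(d, 500)
  rows <- do.call(rbind, lapply(1:2, function(r) {
    sim <- run_adaptation(b$state, trait_params(0.9, 50), d)
    summarize_replicate(sim, null, V_G0)
  }))
  expect_identical(nrow(rows), 2L)
  expect_true(all(c("time_to_optimum", "prop_sweeps", "n_segregating",
                    "V_G_final") %in% names(rows)))
  agg <- aggregate_summaries(rows)
  expect_identical(nrow(agg), 1L)
  expect_identical(agg$n_replicates, 2L)
  expect_equal(agg$V_G_final, mean(rows$V_G_final))
})
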