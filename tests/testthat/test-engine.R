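focal <- trait_params(sigma_m = 0.05, V_S = 1)

test_that("population size follows the schedule", {
  set.seed(10)
  st <- new_population(50)
  st2 <- advance_generation(st, focal, schedule = c(50, 50, 50))
  expect_length(st2$G, 50)
  st3 <- advance_generation(st2, focal, schedule = c(30, 80))
  expect_length(st3$G, 80)
})

test_that("no mutation means no genetic variance, ever", {
  set.seed(11)
  b <- run_burn_in(focal, demography_model(100), qtl_layout(U = 0),
                   generations = 200)
  expect_true(all(b$trajectory$var_G == 0))
  expect_identical(nrow(b$state$mutations), 0L)
})

test_that("stored genetic values and allele counts match gamete contents", {
  set.seed(12)
  b <- run_burn_in(focal, demography_model(150), generations = 1500)
  st <- b$state
  # G recomputed from mutation sets + baseline reproduces stored G exactly
  expect_equal(recompute_genetic_values(st), st$G, tolerance = 1e-12)
  # allele counts equal the tally over all gametes
  tal <- tally_allele_counts(st)
  expect_identical(as.integer(tal[seq_len(nrow(st$mutations))]),
                   st$mutations$count)
  expect_true(all(st$mutations$count >= 1 &
                  st$mutations$count <= 2 * length(st$G)))
  # the same holds on snapshots taken during adaptation
  sim <- run_adaptation(st, focal, demography_model(150),
                        genotypes_in_snapshots = TRUE)
  snap <- sim$snapshots[[1]]
  expect_equal(recompute_genetic_values(snap), snap$G, tolerance = 1e-12)
  tal <- tally_allele_counts(snap)
  expect_identical(as.integer(tal[snap$mutations$slot]),
                   snap$mutations$count)
})

test_that("neutral allele-frequency change is Wright-Fisher", {
  # all effects zero: one generation of reproduction changes a mutation's
  # frequency with mean 0 and variance p(1-p)/2N (binomial oracle)
  N <- 100
  p <- 0.3
  set.seed(13)
  dp <- replicate(3000, {
    st <- state_with_mutations(N, counts = round(2 * N * p))
    st2 <- advance_generation(st, focal, schedule = N,
                              layout = qtl_layout(U = 0))
    if (nrow(st2$mutations) == 0) -p  # lost (or fixed; p' recorded as 0)
    else st2$mutations$count[1] / (2 * N) - p
  })
  expect_lt(abs(mean(dp)), 3 * sqrt(p * (1 - p) / (2 * N) / 3000))
  expect_equal(var(dp), p * (1 - p) / (2 * N), tolerance = 0.1)
})

test_that("fixed mutations persist through the baseline", {
  # a near-fixed strongly beneficial allele fixes and its full homozygous
  # effect (2a) moves into the baseline, still visible in later trait means
  N <- 60
  set.seed(14)
  st <- state_with_mutations(N, counts = 2 * N - 1, effects = 0.5)
  params <- trait_params(sigma_m = 0.05, V_S = 1, z_opt_initial = 1)
  st2 <- advance_generation(st, params, schedule = rep(N, 30),
                            layout = qtl_layout(U = 0))
  expect_identical(nrow(st2$mutations), 0L)  # fixed (or lost) by now
  expect_equal(st2$baseline, 2 * 0.5)
  expect_equal(mean(st2$G), 1)
})

test_that("identical seeds reproduce identical runs", {
  run <- function() {
    set.seed(99)
    b <- run_burn_in(focal, demography_model(80), generations = 300)
    sim <- run_adaptation(b$state, focal, demography_model(80))
    list(b$trajectory, sim$trajectory, sim$fixations, sim$segregating)
  }
  expect_identical(run(), run())
})

test_that("positive alleles rise and negative alleles fall under truncation", {
  # directional phase of the optimum shift: large-positive-effect standing
  # alleles gain frequency, negative ones lose it (sign test over sites)
  N <- 300
  set.seed(15)
  up <- 0L; down <- 0L
  for (r in 1:8) {
    eff <- c(rep(0.4, 3), rep(-0.4, 3))
    st <- state_with_mutations(N, counts = rep(round(0.2 * 2 * N), 6),
                               effects = eff, loci = 1:6)
    st2 <- advance_generation(st, trait_params(0.05, 1), schedule = rep(N, 5),
                              phase = "truncation",
                              layout = qtl_layout(U = 0))
    m <- st2$mutations
    for (l in 1:6) {
      row <- which(m$locus == l)
      p_new <- if (length(row)) m$count[row] / (2 * N) else
        if (st2$baseline > 0 && eff[l] > 0) 1 else 0  # fixed or lost
      dp <- p_new - 0.2
      if (eff[l] > 0 && dp > 0) up <- up + 1L
      if (eff[l] < 0 && dp < 0) down <- down + 1L
    }
  }
  expect_gt(up, 18)    # 24 positive sites total
  expect_gt(down, 18)  # 24 negative sites total
})

test_that("adaptation switches from truncation to stabilizing at the optimum", {
  set.seed(16)
  b <- run_burn_in(trait_params(0.9, 50), demography_model(400))
  sim <- run_adaptation(b$state, trait_params(0.9, 50),
                        demography_model(400))
  tr <- sim$trajectory
  expect_false(is.na(sim$reached_gen))
  # truncation active before, inactive after the exit generation
  expect_true(all(tr$truncation[tr$generation <= sim$reached_gen] == 1))
  expect_true(all(tr$truncation[tr$generation > sim$reached_gen] == 0))
  # null shift: optimum unchanged -> no truncation, mean stays near 0
  params0 <- trait_params(0.05, 1, z_opt_new = 0)
  sim0 <- run_adaptation(b$state, params0, demography_model(400))
  expect_true(all(sim0$trajectory$truncation == 0))
  expect_lt(max(abs(sim0$trajectory$mean_trait)), 2)
})
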