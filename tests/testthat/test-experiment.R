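test_that("presets bind the documented parameter values", {
  t1 <- preset("maize-trait1")
  expect_equal(c(t1$params$sigma_m, t1$params$V_S, t1$params$psi),
               c(0.01, 1, 0))
  expect_equal(t1$demography$bottleneck_frac, 0.05)
  expect_equal(t1$demography$final_mult, 10)
  t2 <- preset("maize-trait2")
  expect_equal(c(t2$params$sigma_m, t2$params$V_S), c(0.9, 50))
  s <- preset("single-scenario")
  expect_equal(c(s$params$sigma_m, s$params$V_S, s$params$psi),
               c(0.05, 1, 0))
  expect_equal(s$demography$N_bottleneck, s$demography$N_anc)
  expect_true(all(list_presets() %in%
                  c("single-scenario", "maize-trait1", "maize-trait2")))
})

test_that("demography schedules bottleneck then grow exponentially", {
  d <- demography_model(1000, bottleneck_frac = 0.05, final_mult = 10)
  expect_identical(d$schedule[d$T_adapt], 10000L)
  expect_identical(d$N_bottleneck, 50L)
  # exponential interpolation in between (monotone, correct midpoint)
  expect_true(all(diff(d$schedule) >= 0))
  mid <- d$schedule[d$T_adapt / 2]
  expect_equal(mid, sqrt(50 * 10000), tolerance = 0.01)
  # no bottleneck, no growth: flat schedule
  d0 <- demography_model(500)
  expect_true(all(d0$schedule == 500L))
})

test_that("the full study grid expands to 1200 parameter sets", {
  g <- expand_parameter_grid(default_config())
  expect_identical(nrow(g), 1200L)
  expect_identical(anyDuplicated(g[, 1:5]), 0L)
  expect_identical(nrow(demography_grid()), 12L)
  expect_identical(nrow(unique(g[, c("bottleneck_frac", "final_mult")])),
                   12L)
})

test_that("config files override defaults field by field", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("N_anc: 250", "replicates: 2", "grid:",
               "  sigma_m: [0.05, 0.9]", "  psi: [0]"), cfg_file)
  cfg <- read_config(cfg_file)
  expect_identical(cfg$N_anc, 250L)
  expect_identical(cfg$replicates, 2L)
  expect_equal(cfg$grid$sigma_m, c(0.05, 0.9))
  expect_equal(cfg$grid$psi, 0)
  expect_equal(cfg$grid$V_S, c(1, 5, 10, 20, 50))  # untouched default
})

test_that("a mini-grid run produces all stages deterministically", {
  grid <- expand_parameter_grid(list(grid = list(
    sigma_m = c(0.1, 0.9), V_S = 5, psi = 0,
    bottleneck_frac = c(1, 0.1), final_mult = 1)))
  expect_identical(nrow(grid), 4L)
  out_dir <- withr::local_tempdir()
  res <- run_experiment(grid, N_anc = 100, replicates = 2, n_null = 300,
                        seed = 5, out_dir = out_dir, burn_in_gens = 600)
  expect_identical(nrow(res$summaries), 8L)
  expect_identical(nrow(res$aggregate), 4L)
  expect_length(res$nulls, 2L)
  expect_length(res$manifest$runs, 8L)
  expect_true(all(file.exists(file.path(out_dir,
    c("summary.tsv", "aggregate.tsv", "null.tsv", "manifest.json")))))
  # re-running with the same seed reproduces the tables byte-identically
  out_dir2 <- withr::local_tempdir()
  res2 <- run_experiment(grid, N_anc = 100, replicates = 2, n_null = 300,
                         seed = 5, out_dir = out_dir2, burn_in_gens = 600)
  for (f in c("summary.tsv", "aggregate.tsv", "null.tsv", "manifest.json"))
    expect_identical(readLines(file.path(out_dir, f)),
                     readLines(file.path(out_dir2, f)))
  # burn-in sharing: identical (sigma_m, V_S) start from the same state
  expect_identical(
    res$summaries$V_G0[res$summaries$set_id == grid$set_id[1]],
    res$summaries$V_G0[res$summaries$set_id == grid$set_id[3]])
})
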