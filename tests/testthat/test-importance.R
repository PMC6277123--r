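# synthetic tables driven by known parameter-to-statistic maps
driver_table <- function(n = 300, seed = 60) {
  set.seed(seed)
  data.frame(
    sigma_m = sample(c(0.01, 0.05, 0.1, 0.3, 0.9), n, TRUE),
    V_S = sample(c(1, 5, 10, 20, 50), n, TRUE),
    psi = sample(c(0, 0.1, 0.5, 0.95), n, TRUE),
    bottleneck_frac = sample(c(1, 0.1, 0.05, 0.01), n, TRUE),
    final_mult = sample(c(1, 3, 10), n, TRUE)
  )
}

test_that("a single-driver target gives that driver the importance", {
  tab <- driver_table()
  tab$stat <- log(tab$sigma_m)          # deterministic in sigma_m only
  res <- suppressWarnings(fit_importance(tab, "stat", seed = 1))
  expect_gt(res$importance[["sigma_m"]], 0.95)
  expect_equal(sum(res$importance), 1)
  expect_true(all(res$importance >= 0))
  expect_gt(res$r_squared, 0.99)
  expect_lt(res$nrmsd, 0.05)
})

test_that("pure noise yields no predictive accuracy", {
  tab <- driver_table(seed = 61)
  set.seed(62)
  tab$stat <- rnorm(nrow(tab))
  res <- fit_importance(tab, "stat", seed = 2)
  expect_lt(res$r_squared, 0.15)
  expect_equal(sum(res$importance), 1)
})

test_that("an added pure-noise feature ranks below every real driver", {
  # every input parameter carries signal; the noise feature (discrete like
  # the real ones, to keep impurity importances comparable) carries none
  tab <- driver_table(seed = 63)
  set.seed(64)
  tab$noise_feature <- sample(c(0.1, 0.2, 0.3, 0.4), nrow(tab), TRUE)
  tab$stat <- tab$sigma_m + 0.5 * tab$psi + 0.2 * log(tab$V_S) +
    0.4 * tab$bottleneck_frac + 0.1 * log(tab$final_mult)
  res <- fit_importance(tab, "stat",
                        features = c("sigma_m", "V_S", "psi",
                                     "bottleneck_frac", "final_mult",
                                     "noise_feature"),
                        seed = 3)
  expect_identical(names(which.min(res$importance)), "noise_feature")
})

test_that("cross validation scores a learnable step function near 1", {
  tab <- driver_table(seed = 65)
  tab$stat <- ifelse(tab$sigma_m > 0.05, 2, -1)
  cv <- suppressWarnings(
    cross_validate(tab[, 1:5], tab$stat, folds = 10, seed = 4))
  expect_gt(cv$r_squared, 0.98)
  expect_lt(cv$nrmsd, 0.05)
  expect_error(cross_validate(tab[1:5, 1:5], tab$stat[1:5], folds = 10),
               "fewer rows")
})

test_that("NRMSD of an unpredictable uniform target is near sd/range", {
  # features carry no signal, so the forest predicts ~the mean; for a
  # uniform target RMSE/range ~ sd/range = 1/sqrt(12) ~ 0.289
  tab <- driver_table(n = 400, seed = 66)
  set.seed(67)
  tab$stat <- runif(nrow(tab))
  cv <- cross_validate(tab[, 1:5], tab$stat, seed = 5)
  expect_equal(cv$nrmsd, 1 / sqrt(12), tolerance = 0.2)
})

test_that("importance is reproducible for identical seeds", {
  tab <- driver_table(seed = 68)
  tab$stat <- tab$sigma_m + tab$psi
  r1 <- fit_importance(tab, "stat", seed = 7)
  r2 <- fit_importance(tab, "stat", seed = 7)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$r_squared, r2$r_squared)
})

test_that("constant targets are rejected", {
  tab <- driver_table(seed = 69)
  tab$stat <- 1
  expect_error(fit_importance(tab, "stat"), "constant")
})

test_that("architecture importance aggregates per-cell forests", {
  # matrices depending only on final_mult: that feature dominates
  tab <- driver_table(n = 120, seed = 70)
  for (k in 1:6)
    tab[[paste0("cell_", k)]] <- (k / 6) * log(tab$final_mult + k)
  res <- suppressWarnings(architecture_importance(tab, n_trees = 50, seed = 8))
  expect_equal(sum(res$aggregate), 1)
  expect_identical(names(which.max(res$aggregate)), "final_mult")
  expect_gt(res$aggregate[["final_mult"]], 0.9)
})
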