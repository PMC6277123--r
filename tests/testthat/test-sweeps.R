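fix_table <- function(origin, gen, effect = rep(0.1, length(origin))) {
  n <- length(origin)
  data.frame(locus = rep(1L, n), pos = rep(1, n), effect = effect,
             origin = origin, gen = gen,
             p0 = ifelse(origin <= 0, 0.1, 0))
}

test_that("sweep classification applies the threshold and origin rules", {
  thr <- 100
  cls <- classify_fixations(
    fix_table(origin = c(-50, 5, -200, 30),
              gen = c(10, 45, 300, 35)), thr)
  # sojourns: 60, 40, 500, 5
  expect_identical(cls$classification,
                   c("standing_sweep", "hard_sweep", "non_sweep",
                     "hard_sweep"))
  # sojourn >= threshold is never a sweep regardless of origin
  cls2 <- classify_fixations(fix_table(origin = c(-500, 20),
                                       gen = c(40, 400)), thr)
  expect_identical(cls2$classification, c("non_sweep", "non_sweep"))
  # burn-in fixations must have been excluded upstream
  expect_error(classify_fixations(fix_table(origin = -10, gen = 0), thr),
               "excluded")
})

test_that("sweep classes partition the fixations exactly", {
  set.seed(30)
  n <- 200
  tab <- fix_table(origin = sample(-300:50, n, replace = TRUE),
                   gen = sample(1:400, n, replace = TRUE))
  tab <- tab[tab$gen > tab$origin, ]
  cls <- classify_fixations(tab, 150)
  sm <- sweep_summary(cls, 10)
  expect_identical(sm$n_hard + sm$n_standing +
                     sum(cls$classification == "non_sweep"),
                   nrow(tab))
  # permutation invariance
  perm <- sample(nrow(tab))
  cls_p <- classify_fixations(tab[perm, ], 150)
  expect_identical(cls_p$classification, cls$classification[perm])
  # hard implies post-shift origin; standing implies pre-shift origin
  expect_true(all(cls$origin[cls$classification == "hard_sweep"] > 0))
  expect_true(all(cls$origin[cls$classification == "standing_sweep"] <= 0))
})

test_that("lowering the threshold never increases the sweep count", {
  set.seed(31)
  tab <- fix_table(origin = sample(-300:50, 150, replace = TRUE),
                   gen = sample(1:400, 150, replace = TRUE))
  tab <- tab[tab$gen > tab$origin, ]
  counts <- vapply(c(400, 200, 100, 50, 10), function(thr)
    sweep_summary(classify_fixations(tab, thr))$n_sweeps, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sweep summary handles edge cases and proportions", {
  # no fixations: counts 0, proportions missing (not 0)
  empty <- classify_fixations(fix_table(integer(0), integer(0)), 10)
  sm <- sweep_summary(empty, 10)
  expect_identical(sm$n_fixations, 0L)
  expect_true(is.na(sm$prop_sweeps) && is.na(sm$prop_standing))
  # all fast pre-shift fixations: both proportions are 1
  all_sw <- classify_fixations(fix_table(origin = c(-5, -9),
                                         gen = c(3, 4)), 1000)
  sm2 <- sweep_summary(all_sw, 10)
  expect_identical(c(sm2$prop_sweeps, sm2$prop_standing), c(1, 1))
})

test_that("shift-anchored sojourn is a sensitivity option", {
  tab <- fix_table(origin = -500, gen = 80)
  # origin-anchored: sojourn 580 >= 100 -> non-sweep
  expect_identical(classify_fixations(tab, 100)$classification, "non_sweep")
  # shift-anchored: sojourn 80 < 100 -> standing sweep
  cls <- classify_fixations(tab, 100, sojourn_from = "shift")
  expect_identical(cls$classification, "standing_sweep")
})
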