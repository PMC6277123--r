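sym_effects <- function(n) {
  x <- abs(rnorm(n))
  c(-x, x)
}

test_that("effect bin edges are symmetric quantiles around zero", {
  set.seed(50)
  eff <- sym_effects(5000)
  e <- effect_bin_edges(eff)
  expect_length(e, 8)
  expect_true(all(diff(e) > 0))
  # symmetry of the input gives (approximately) mirrored edges
  expect_equal(e[4], -e[5])
  expect_equal(e[1:3], -rev(e[6:8]), tolerance = 0.05)
  # scaling all effects scales all edges
  e3 <- effect_bin_edges(3 * eff)
  expect_equal(e3, 3 * e, tolerance = 1e-10)
  expect_error(effect_bin_edges(rep(c(-1, 1), 10)), "distinct")
})

test_that("architecture matrix is a normalized 7 x 9 occupancy table", {
  set.seed(51)
  eff <- sym_effects(2000)
  edges <- effect_bin_edges(eff)
  seg <- data.frame(frequency = runif(4000), effect = sample(eff, 4000, TRUE))
  m <- build_architecture_matrix(seg, edges)
  expect_identical(dim(unclass(m)), c(7L, 9L))
  expect_equal(sum(m), 1)
  expect_true(all(m >= 0))
  # a single site occupies exactly one cell with weight 1
  one <- build_architecture_matrix(data.frame(frequency = 0.3, effect = 0),
                                   edges)
  expect_equal(sum(one == 1), 1)
  expect_equal(sum(one), 1)
  # half-open frequency bins: a site at exactly 0.1 falls in [0.1, 0.5)
  at_edge <- build_architecture_matrix(
    data.frame(frequency = 0.1, effect = 0), edges)
  expect_equal(unname(rowSums(at_edge)["0.1-0.5"]), 1)
  # sites at 0 or 1 are not segregating
  none <- build_architecture_matrix(
    data.frame(frequency = c(0, 1), effect = c(0, 0)), edges)
  expect_true(attr(none, "empty"))
  # permutation invariance
  perm <- sample(nrow(seg))
  expect_equal(unclass(build_architecture_matrix(seg[perm, ], edges)),
               unclass(m))
})

test_that("mirror symmetry of effects mirrors matrix occupancy", {
  set.seed(52)
  x <- abs(rnorm(3000))
  seg <- data.frame(frequency = rep(runif(3000), 2), effect = c(-x, x))
  m <- build_architecture_matrix(seg, effect_bin_edges(seg$effect))
  left <- unclass(m)[, 1:4]
  right <- unclass(m)[, 9:6]
  expect_equal(sum(left), sum(right), tolerance = 0.05)
})

test_that("matrix correlations behave as Pearson over cells", {
  set.seed(53)
  eff <- sym_effects(2000)
  edges <- effect_bin_edges(eff)
  seg1 <- data.frame(frequency = runif(3000),
                     effect = sample(eff, 3000, TRUE))
  seg2 <- data.frame(frequency = runif(3000)^2,
                     effect = sample(eff, 3000, TRUE))
  A <- build_architecture_matrix(seg1, edges)
  B <- build_architecture_matrix(seg2, edges)
  expect_equal(matrix_correlation(A, A), 1)
  r <- matrix_correlation(A, B)
  expect_equal(r, cor(as.vector(unclass(A)), as.vector(unclass(B))))
  # uniform matrix has zero variance: undefined correlation
  U <- matrix(1 / 63, 7, 9)
  expect_true(is.na(matrix_correlation(U, U)))

  pw <- pairwise_correlations(list(a = A, b = B, c = A))
  expect_equal(diag(pw), c(a = 1, b = 1, c = 1))
  expect_equal(pw, t(pw))
  expect_equal(pw["a", "c"], 1)
})

test_that("replicate-mean matrices are renormalized means", {
  set.seed(54)
  eff <- sym_effects(1000)
  edges <- effect_bin_edges(eff)
  ms <- lapply(1:3, function(i)
    build_architecture_matrix(
      data.frame(frequency = runif(500), effect = sample(eff, 500, TRUE)),
      edges))
  mm <- mean_architecture(ms)
  expect_equal(sum(mm), 1)
  expect_equal(matrix(mm, 7, 9),
               matrix(Reduce(`+`, lapply(ms, unclass)) / 3, 7, 9),
               tolerance = 1e-12)
})
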