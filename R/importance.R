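# Parameter-importance analysis: ensemble-of-regression-trees models
# predicting each summary statistic (or architecture-matrix cell) from the
# swept input parameters, with impurity-based importances normalized to
# sum to 1 and 10-fold cross-validated accuracy.

DEFAULT_FEATURES <- c("sigma_m", "V_S", "psi", "bottleneck_frac",
                      "final_mult")

#' Fit a random-forest importance model for one target statistic
#'
#' Trains a 100-tree random-forest regression of `target` on the input
#' parameters over the whole table, extracts impurity-based (node-purity)
#' feature importances normalized to sum to 1, and reports 10-fold
#' cross-validated R-squared and NRMSD. All trees consider every feature
#' at each split (`mtry = p`), and the fit is deterministic given `seed`.
#'
#' @param table Summary table (one row per replicate or parameter set).
#' @param target Name of the target statistic column.
#' @param features Feature column names; `V_S` can be swapped for `V_G0`
#'   (both encodings are meaningful; see the methods vignette).
#' @param n_trees Number of trees (default 100).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling forest and fold randomness.
#' @return An `importance_result`: `target`, `importance` (named, sums to
#'   1), `r_squared`, `nrmsd`, `n`.
#' @export
fit_importance <- function(table, target, features = DEFAULT_FEATURES,
                           n_trees = 100, folds = 10, seed = 1) {
  stopifnot(target %in% names(table), all(features %in% names(table)))
  dat <- table[stats::complete.cases(table[, c(features, target)]),
               c(features, target), drop = FALSE]
  y <- dat[[target]]
  if (length(unique(y)) < 2)
    stop("target '", target, "' is constant; importance is undefined")
  x <- dat[, features, drop = FALSE]
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = length(features),
    importance = FALSE)
  imp <- fit$importance[, "IncNodePurity"]
  if (sum(imp) <= 0) imp[] <- 1 / length(imp) else imp <- imp / sum(imp)
  cv <- cross_validate(x, y, n_trees = n_trees, folds = folds,
                       seed = seed + 1L)
  structure(
    list(target = target, importance = imp,
         r_squared = cv$r_squared, nrmsd = cv$nrmsd, n = nrow(dat),
         features = features),
    class = "importance_result"
  )
}

#' Cross-validated accuracy of a random-forest regression
#'
#' K-fold cross validation: the forest is refit on each training split and
#' out-of-fold predictions are pooled; R-squared and NRMSD (root mean
#' squared deviation divided by the observed target range) are computed on
#' the pooled predictions. R-squared can be misleading for targets whose
#' values concentrate near zero, which is why NRMSD is always reported
#' alongside.
#'
#' @param x Feature data.frame.
#' @param y Numeric target.
#' @param n_trees Trees per fold.
#' @param folds Number of folds; must not exceed the number of rows.
#' @param seed Integer seed.
#' @return List with `r_squared` and `nrmsd`.
#' @export
cross_validate <- function(x, y, n_trees = 100, folds = 10, seed = 1) {
  n <- length(y)
  if (n < folds) stop("fewer rows than folds")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- randomForest::randomForest(
      x = x[!test, , drop = FALSE], y = y[!test],
      ntree = n_trees, mtry = ncol(x))
    pred[test] <- stats::predict(fit, x[test, , drop = FALSE])
  }
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  rng <- diff(range(y))
  list(r_squared = 1 - ss_res / ss_tot,
       nrmsd = if (rng > 0) sqrt(mean((y - pred)^2)) / rng else NA_real_)
}

#' Parameter importance for the genetic architecture
#'
#' Predicts each of the 63 architecture-matrix cell frequencies from the
#' input parameters with its own random forest, then aggregates the
#' normalized per-cell importances (mean over cells, renormalized).
#' Constant cells (e.g. never-occupied bins) are skipped.
#'
#' @param cell_table Data.frame with feature columns plus one column per
#'   matrix cell (cells prefixed `cell_`), one row per parameter set (or
#'   replicate).
#' @param features Feature column names.
#' @param n_trees,seed Forest settings as in [fit_importance()].
#' @return List with `aggregate` (named importances summing to 1),
#'   `per_cell` (matrix: cells x features), and `cells_used`.
#' @export
architecture_importance <- function(cell_table, features = DEFAULT_FEATURES,
                                    n_trees = 100, seed = 1) {
  cells <- grep("^cell_", names(cell_table), value = TRUE)
  stopifnot(length(cells) > 0)
  x <- cell_table[, features, drop = FALSE]
  per_cell <- list()
  for (cn in cells) {
    y <- cell_table[[cn]]
    if (length(unique(y)) < 2) next
    set.seed(seed)
    fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                      mtry = length(features))
    imp <- fit$importance[, "IncNodePurity"]
    if (sum(imp) > 0) per_cell[[cn]] <- imp / sum(imp)
  }
  if (length(per_cell) == 0L) stop("all architecture cells are constant")
  pc <- do.call(rbind, per_cell)
  agg <- colMeans(pc)
  agg <- agg / sum(agg)
  list(aggregate = agg, per_cell = pc, cells_used = rownames(pc))
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Importance for", x$target, "(n =", x$n, ")\n")
  imp <- sort(x$importance, decreasing = TRUE)
  for (nm in names(imp))
    cat(sprintf("  %-16s %5.1f%%\n", nm, 100 * imp[nm]))
  cat(sprintf("  CV R^2 = %.3f | NRMSD = %.3f\n", x$r_squared, x$nrmsd))
  invisible(x)
}
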