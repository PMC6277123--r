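# Genetic-architecture matrices: the joint distribution of segregating
# sites over 7 allele-frequency bins and 9 effect-size bins, normalized to
# sum to 1, and comparisons between matrices.

FREQ_EDGES <- c(0, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 0.9, 1)
FREQ_LABELS <- c("0-1e-4", "1e-4-1e-3", "1e-3-1e-2", "1e-2-0.1",
                 "0.1-0.5", "0.5-0.9", "0.9-1")

#' Effect-size bin edges from pooled effects
#'
#' Nine quantile bins centered on zero: the central bin spans `(-q, +q)`
#' with `q` the `central_prob` quantile of the pooled absolute effects
#' (default 1/9, giving roughly equal occupancy across the nine bins on a
#' symmetric effect distribution), and the remaining negative and positive
#' effects are split into four equal-count quantile bins on each side.
#' Edges are computed from the effects pooled over all replicates of one
#' parameter set so that replicate matrices are comparable.
#'
#' @param effects Pooled segregating effect sizes.
#' @param central_prob Probability mass of `|effects|` inside the central
#'   bin.
#' @return Strictly increasing vector of 8 interior edges.
#' @export
effect_bin_edges <- function(effects, central_prob = 1 / 9) {
  effects <- effects[is.finite(effects)]
  if (length(unique(effects)) < 9)
    stop("need at least 9 distinct effect sizes to build quantile bins")
  q <- stats::quantile(abs(effects), central_prob, names = FALSE)
  neg <- effects[effects <= -q]
  pos <- effects[effects >= q]
  qs <- c(0.25, 0.5, 0.75)
  neg_edges <- stats::quantile(neg, qs, names = FALSE)
  pos_edges <- stats::quantile(pos, qs, names = FALSE)
  edges <- c(neg_edges, -q, q, pos_edges)
  if (any(diff(edges) <= 0))
    stop("degenerate effect-size bins: edges are not strictly increasing")
  edges
}

#' Build a genetic-architecture matrix
#'
#' Assigns every segregating site to one of 7 x 9 frequency-by-effect
#' cells and normalizes by the total site count, so entries are relative
#' occurrence frequencies summing to 1. Frequency bins are half-open
#' `[lo, hi)` with the last bin `[0.9, 1)` closed on the left only (sites
#' at exactly 0 or 1 are not segregating and are excluded); effect bins
#' come from [effect_bin_edges()].
#'
#' @param segregating Table with `frequency` and `effect` columns (or a
#'   snapshot list with `mutations` and `n`).
#' @param edges Effect-size edges from [effect_bin_edges()].
#' @return An `architecture_matrix`: 7 x 9 numeric matrix with an
#'   `n_sites` attribute (`empty` flag when no sites exist).
#' @export
build_architecture_matrix <- function(segregating, edges) {
  stopifnot(length(edges) == 8, all(diff(edges) > 0))
  if (is.list(segregating) && !is.null(segregating$mutations)) {
    segregating <- data.frame(
      frequency = segregating$mutations$count / (2 * segregating$n),
      effect = segregating$mutations$effect)
  }
  keep <- segregating$frequency > 0 & segregating$frequency < 1
  fr <- segregating$frequency[keep]
  ef <- segregating$effect[keep]
  m <- matrix(0, nrow = 7, ncol = 9,
              dimnames = list(FREQ_LABELS, paste0("E", 1:9)))
  if (length(fr) == 0L) {
    attr(m, "n_sites") <- 0L
    attr(m, "empty") <- TRUE
    class(m) <- c("architecture_matrix", class(m))
    return(m)
  }
  fbin <- findInterval(fr, FREQ_EDGES)          # [lo, hi): default semantics
  fbin[fbin > 7] <- 7L                          # freq exactly edge-adjacent
  ebin <- findInterval(ef, edges) + 1L          # 1..9
  for (i in seq_along(fr)) m[fbin[i], ebin[i]] <- m[fbin[i], ebin[i]] + 1
  m <- m / length(fr)
  attr(m, "n_sites") <- length(fr)
  attr(m, "empty") <- FALSE
  class(m) <- c("architecture_matrix", class(m))
  m
}

#' Mean architecture matrix over replicates
#'
#' Per-parameter-set matrix: the mean of the replicate matrices,
#' renormalized to sum to 1 (empty replicates are dropped).
#'
#' @param matrices List of `architecture_matrix` objects.
#' @return An `architecture_matrix`.
#' @export
mean_architecture <- function(matrices) {
  keep <- !vapply(matrices, function(m) isTRUE(attr(m, "empty")), logical(1))
  matrices <- matrices[keep]
  if (length(matrices) == 0L) stop("no non-empty architecture matrices")
  m <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  m <- m / sum(m)
  attr(m, "n_sites") <- sum(vapply(matrices,
                                   function(x) attr(x, "n_sites"),
                                   numeric(1)))
  attr(m, "empty") <- FALSE
  class(m) <- c("architecture_matrix", class(m))
  m
}

#' Correlation between two architecture matrices
#'
#' Pearson correlation of the 63 paired cell frequencies. `NA` when either
#' matrix has zero variance across cells.
#'
#' @param A,B Architecture matrices of identical shape.
#' @return Correlation coefficient, or `NA`.
#' @export
matrix_correlation <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  a <- as.vector(unclass(A))
  b <- as.vector(unclass(B))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Pairwise correlations of architecture matrices
#'
#' @param matrices Named list of (replicate-mean) architecture matrices,
#'   one per parameter set.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  k <- length(matrices)
  out <- matrix(NA_real_, k, k,
                dimnames = list(names(matrices), names(matrices)))
  for (i in seq_len(k)) {
    out[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      r <- matrix_correlation(matrices[[i]], matrices[[j]])
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  out
}

#' @export
print.architecture_matrix <- function(x, ...) {
  cat("Genetic-architecture matrix (7 frequency x 9 effect bins),",
      attr(x, "n_sites"), "sites\n")
  print(round(unclass(x), 4))
  invisible(x)
}
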