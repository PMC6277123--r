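# Gamete-level operations in plain R. A gamete is a data.frame with columns
# locus (integer, 1-based), pos (continuous bp within locus) and effect.
# These functions mirror the transmission model used by the compiled engine
# and are what the unit tests exercise directly.

#' An empty gamete
#' @return A zero-row gamete data.frame.
#' @export
empty_gamete <- function() {
  data.frame(locus = integer(0), pos = numeric(0), effect = numeric(0))
}

#' Add new mutations to a gamete
#'
#' The number of new trait mutations is Poisson with mean `layout$U` (the
#' total per-gamete rate). Each mutation picks a region uniformly, then
#' lands in the genic core vs the intergenic flanks with probability
#' proportional to length times per-site rate (intergenic sites mutate at
#' 1% of the genic rate), at a continuous position: the infinitely-many-
#' sites assumption, so no site is ever hit twice.
#'
#' @param gamete A gamete data.frame.
#' @param layout A [qtl_layout()].
#' @param sigma_m Effect-size standard deviation for new mutations.
#' @return The gamete with any new mutations appended (sorted by locus, pos).
#' @export
mutate_gamete <- function(gamete, layout, sigma_m) {
  n_new <- stats::rpois(1, layout$U)
  if (n_new == 0L) return(gamete)
  locus <- sample.int(layout$n_loci, n_new, replace = TRUE)
  flank <- (layout$locus_len - layout$genic_len) / 2
  genic <- stats::runif(n_new) < layout$genic_frac
  pos <- numeric(n_new)
  pos[genic] <- flank + stats::runif(sum(genic)) * layout$genic_len
  u <- stats::runif(sum(!genic)) * (layout$locus_len - layout$genic_len)
  pos[!genic] <- ifelse(u < flank, u, u + layout$genic_len)
  eff <- if (sigma_m > 0) draw_effect_size(n_new, sigma_m) else numeric(n_new)
  out <- rbind(gamete,
               data.frame(locus = locus, pos = pos, effect = eff))
  out[order(out$locus, out$pos), , drop = FALSE]
}

#' Recombine two parental gametes
#'
#' Regions are unlinked: each region independently starts from one of the
#' two parental gametes with probability 1/2. Within a region, the
#' crossover count is Poisson with mean `locus_len * rec_rate` (2.5e-3 for
#' the default layout; 0.05 summed over the gamete), breakpoints are
#' uniform, and the source gamete switches at each breakpoint.
#'
#' @param g1,g2 Parental gamete data.frames.
#' @param layout A [qtl_layout()].
#' @return A recombinant gamete data.frame.
#' @export
recombine <- function(g1, g2, layout) {
  per_locus_xo <- layout$locus_len * layout$rec_rate
  pieces <- vector("list", layout$n_loci)
  for (l in seq_len(layout$n_loci)) {
    s1 <- g1[g1$locus == l, , drop = FALSE]
    s2 <- g2[g2$locus == l, , drop = FALSE]
    first <- stats::runif(1) < 0.5
    k <- stats::rpois(1, per_locus_xo)
    if (k == 0L) {
      pieces[[l]] <- if (first) s1 else s2
    } else {
      bp <- sort(stats::runif(k) * layout$locus_len)
      # segment index for every position: even = start gamete, odd = other
      seg1 <- findInterval(s1$pos, bp)
      seg2 <- findInterval(s2$pos, bp)
      keep1 <- if (first) seg1 %% 2 == 0 else seg1 %% 2 == 1
      keep2 <- if (first) seg2 %% 2 == 1 else seg2 %% 2 == 0
      piece <- rbind(s1[keep1, , drop = FALSE], s2[keep2, , drop = FALSE])
      pieces[[l]] <- piece[order(piece$pos), , drop = FALSE]
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Phenotype from genetic value and heritable background
#'
#' The trait value is a weighted sum of the explicitly simulated QTL
#' genetic value `G` and a genomic background drawn around the mid-parent
#' value:
#' \deqn{G_B \sim N(G_{mp}, \sigma^2), \qquad
#'       P = \psi G_B + (1 - \psi) G}
#' With `psi = 0` the background is switched off and `P = G`.
#'
#' @param G QTL genetic value(s) of the offspring.
#' @param G_mp Mid-parent value(s) the background is centered on.
#' @param sigma2_parental Variance of the parental trait values
#'   (non-negative).
#' @param psi Background weight in `[0, 1]`.
#' @return Trait value(s) `P`.
#' @export
phenotype <- function(G, G_mp, sigma2_parental, psi) {
  stopifnot(psi >= 0, psi <= 1, sigma2_parental >= 0)
  if (psi == 0) return(G)
  n <- max(length(G), length(G_mp))
  G_B <- stats::rnorm(n, mean = G_mp, sd = sqrt(sigma2_parental))
  psi * G_B + (1 - psi) * G
}
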