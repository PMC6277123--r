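#' Trait parameters
#'
#' Bundles the parameters describing the quantitative trait and its
#' selection regime: the standard deviation of effect sizes of new
#' mutations (`sigma_m`), the width of the Gaussian fitness function
#' (`V_S`, larger = weaker stabilizing selection), the proportion of trait
#' variation contributed by the heritable genomic background (`psi`), and
#' the trait optima before and after the shift.
#'
#' @param sigma_m Standard deviation of the zero-mean Gaussian distribution
#'   of new-mutation effect sizes (trait units). Must be positive; `0` is
#'   accepted as the neutral reduction used for simulator validation.
#' @param V_S Variance parameter of the Gaussian fitness function
#'   (trait units squared); must be positive.
#' @param psi Background weight in `[0, 1]`.
#' @param z_opt_initial Trait optimum before the shift (default 0).
#' @param z_opt_new Trait optimum after the shift (default 10).
#' @return An object of class `trait_params`.
#' @export
trait_params <- function(sigma_m = 0.05, V_S = 1, psi = 0,
                         z_opt_initial = 0, z_opt_new = 10) {
  stopifnot(is.numeric(sigma_m), length(sigma_m) == 1L, sigma_m >= 0)
  stopifnot(is.numeric(V_S), length(V_S) == 1L, V_S > 0)
  stopifnot(is.numeric(psi), length(psi) == 1L, psi >= 0, psi <= 1)
  structure(
    list(sigma_m = sigma_m, V_S = V_S, psi = psi,
         z_opt_initial = z_opt_initial, z_opt_new = z_opt_new),
    class = "trait_params"
  )
}

#' Demography: bottleneck at the optimum shift followed by exponential growth
#'
#' The population is held at `N_anc` diploids throughout the burn-in. At
#' generation 0 (the optimum shift) the size drops instantaneously to
#' `N_bottleneck` and then grows exponentially, reaching `N_final` at
#' generation `0.1 * N_anc`:
#' `N(t) = N_bottleneck * (N_final / N_bottleneck)^(t / T)` with
#' `T = 0.1 * N_anc`, rounded to the nearest integer.
#'
#' @param N_anc Ancestral (burn-in) diploid size.
#' @param bottleneck_frac Fraction of `N_anc` remaining immediately after
#'   the shift (1 = no bottleneck).
#' @param final_mult Final size as a multiple of `N_anc`.
#' @return An object of class `demography_model` with the realized
#'   per-generation `schedule` for generations `1 .. 0.1 * N_anc`.
#' @export
demography_model <- function(N_anc = 1000, bottleneck_frac = 1,
                             final_mult = 1) {
  stopifnot(N_anc >= 20, bottleneck_frac > 0, bottleneck_frac <= 1,
            final_mult > 0)
  N_bneck <- max(2L, as.integer(round(N_anc * bottleneck_frac)))
  N_final <- max(2L, as.integer(round(N_anc * final_mult)))
  T_adapt <- as.integer(round(0.1 * N_anc))
  tt <- seq_len(T_adapt)
  schedule <- as.integer(round(
    N_bneck * (N_final / N_bneck)^(tt / T_adapt)
  ))
  schedule <- pmax(schedule, 2L)
  structure(
    list(N_anc = as.integer(N_anc), N_bottleneck = N_bneck,
         N_final = N_final, bottleneck_frac = bottleneck_frac,
         final_mult = final_mult, T_adapt = T_adapt, schedule = schedule),
    class = "demography_model"
  )
}

#' @export
print.demography_model <- function(x, ...) {
  cat("Demography: N_anc =", x$N_anc,
      "| bottleneck to", x$N_bottleneck,
      "| growth to", x$N_final,
      "over", x$T_adapt, "generations\n")
  invisible(x)
}

#' QTL layout
#'
#' Twenty unlinked 50 kb regions, each with a 4 kb genic core centered in
#' the region; intergenic sites mutate at 1% of the genic per-site rate, so
#' the genic fraction of new trait mutations is
#' `genic_len / (genic_len + 0.01 * (locus_len - genic_len))` (about 0.897).
#' The per-gamete trait mutation rate `U` is the authoritative total (the
#' per-site rates are scaled to satisfy it), and the per-gamete crossover
#' mean is `n_loci * locus_len * rec_rate` (0.05 by default); regions
#' themselves assort freely (unlinked).
#'
#' @param n_loci Number of QTL regions.
#' @param locus_len Region length in bp.
#' @param genic_len Genic core length in bp.
#' @param U Total per-gamete trait mutation rate per generation.
#' @param rec_rate Within-region per-site recombination rate per generation.
#' @param intergenic_rel Relative per-site mutation rate of intergenic vs
#'   genic sites.
#' @return An object of class `qtl_layout`.
#' @export
qtl_layout <- function(n_loci = 20, locus_len = 50000, genic_len = 4000,
                       U = 3e-3, rec_rate = 5e-8, intergenic_rel = 0.01) {
  stopifnot(n_loci >= 1, locus_len > genic_len, genic_len > 0, U >= 0,
            rec_rate >= 0, intergenic_rel >= 0)
  eff_len <- genic_len + intergenic_rel * (locus_len - genic_len)
  genic_frac <- genic_len / eff_len
  structure(
    list(n_loci = as.integer(n_loci), locus_len = locus_len,
         genic_len = genic_len, U = U, rec_rate = rec_rate,
         intergenic_rel = intergenic_rel, genic_frac = genic_frac,
         genic_site_rate = U / (n_loci * eff_len),
         xo_mean = n_loci * locus_len * rec_rate),
    class = "qtl_layout"
  )
}
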