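# Demography-matched null distribution of neutral conditional fixation
# (sojourn) times, built by single-locus binomial sampling, and the sweep
# threshold derived from it.

#' Simulate neutral sojourn times under a demography
#'
#' Single-copy neutral mutations are injected at uniformly drawn origin
#' generations over the burn-in plus adaptation window and propagated by
#' binomial (Wright-Fisher) sampling of allele counts through the
#' demography. Only mutations fixing inside the final `0.1 * N_anc`
#' generations are kept (mutations lost, fixed before the end of the
#' burn-in, or still segregating at the end are ignored), and sampling
#' continues until `n_fixations` sojourn times have been collected.
#'
#' Two samplers are available. `method = "binomial"` runs the scheme
#' exactly as described (almost all injections are lost, so it is slow).
#' `method = "conditional"` (default) simulates the same chain conditioned
#' on eventual fixation via its exact h-transform: for a neutral allele the
#' frequency is a martingale and the fixation probability from count `x` is
#' `x / 2N` under any demography, so the conditioned chain has the
#' size-biased transition `x' = 1 + Binomial(2N' - 1, x / 2N)`. Every
#' trajectory fixes, giving the same sojourn distribution far faster; for a
#' constant demography the fix-in-window restriction does not change the
#' sojourn law and is skipped.
#'
#' @param demography A [demography_model()].
#' @param n_fixations Number of conditional fixation times to collect.
#' @param burn_in Length of the constant-size period before the adaptation
#'   window; defaults to `10 * N_anc`.
#' @param method `"conditional"` (fast, default) or `"binomial"` (naive).
#' @param percentile Quantile of the sojourn distribution used as the sweep
#'   threshold (default 0.01: fixations faster than 99% of neutral alleles).
#' @return A `neutral_null` object: `sojourns`, `threshold_gen`,
#'   `demography`, `n`, `percentile`.
#' @export
simulate_neutral_sojourns <- function(demography, n_fixations = 10000,
                                      burn_in = 10 * demography$N_anc,
                                      method = c("conditional", "binomial"),
                                      percentile = 0.01) {
  method <- match.arg(method)
  stopifnot(n_fixations >= 1)
  constant <- demography$bottleneck_frac == 1 && demography$final_mult == 1
  if (method == "conditional" && constant) {
    soj <- cpp_neutral_sojourns_constN(demography$N_anc, n_fixations,
                                       max_generations =
                                         200L * demography$N_anc)
  } else {
    schedule <- c(rep(demography$N_anc, burn_in), demography$schedule)
    soj <- cpp_neutral_sojourns(
      as.integer(schedule), as.integer(n_fixations),
      window_start = as.integer(burn_in),
      conditioned = (method == "conditional"),
      max_tries = 1e10
    )
  }
  structure(
    list(sojourns = soj,
         threshold_gen = stats::quantile(soj, percentile, names = FALSE),
         demography = demography, n = length(soj), percentile = percentile,
         method = method),
    class = "neutral_null"
  )
}

#' Sweep-calling threshold from a neutral null
#'
#' The threshold is the lower `percentile` quantile (default 1st
#' percentile, linear interpolation between order statistics) of the
#' neutral sojourn times: a fixation faster than this fixed faster than
#' 99% of neutral alleles under the same demography.
#'
#' @param null A `neutral_null` object, or a bare numeric vector of
#'   sojourn times.
#' @param percentile Lower tail probability (default 0.01).
#' @return The threshold in generations.
#' @export
sweep_threshold <- function(null, percentile = 0.01) {
  soj <- if (inherits(null, "neutral_null")) null$sojourns else null
  if (length(soj) == 0L) stop("empty neutral null")
  stats::quantile(soj, percentile, names = FALSE)
}

#' @export
print.neutral_null <- function(x, ...) {
  cat("Neutral null:", x$n, "conditional fixation times | mean sojourn",
      format(mean(x$sojourns), digits = 5), "generations | ",
      100 * x$percentile, "% threshold", format(x$threshold_gen, digits = 5),
      "\n")
  invisible(x)
}
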