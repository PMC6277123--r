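# Per-simulation summary statistics: adaptation speed, variance dynamics,
# site frequency spectra, fixation and segregating-site descriptors, and
# the closed-form equilibrium variance expectations.

#' House-of-cards equilibrium genetic variance
#'
#' Deterministic house-of-cards approximation of the equilibrium genetic
#' variance at mutation-selection balance: `E[V_G] = 4 * mu * V_S`, with
#' `mu` the per-gamete trait mutation rate.
#'
#' @param mu_gamete Per-gamete trait mutation rate.
#' @param V_S Stabilizing-selection width.
#' @return Expected equilibrium `V_G`.
#' @export
hoc_expectation <- function(mu_gamete, V_S) 4 * mu_gamete * V_S

#' Stochastic house-of-cards equilibrium genetic variance
#'
#' Finite-population correction of [hoc_expectation()]:
#' `E[V_G] = 4 * mu * V_S / (1 + V_S / (N * sigma_m^2))`. Converges to the
#' deterministic value as `N * sigma_m^2` grows.
#'
#' @inheritParams hoc_expectation
#' @param N Diploid population size.
#' @param sigma_m Effect-size standard deviation of new mutations.
#' @return Expected equilibrium `V_G`.
#' @export
stochastic_hoc_expectation <- function(mu_gamete, V_S, N, sigma_m) {
  4 * mu_gamete * V_S / (1 + V_S / (N * sigma_m^2))
}

#' Time to reach the new optimum
#'
#' First generation at which the population mean trait reaches 99% of the
#' new optimum, expressed in units of `N_anc` generations; `NA` if the
#' optimum is never reached within the simulated window.
#'
#' @param trajectory Trajectory data.frame with `generation` and
#'   `mean_trait`.
#' @param z_opt_new New optimum.
#' @param N_anc Ancestral population size (the time unit).
#' @return Time in `N_anc` units, or `NA`.
#' @export
time_to_optimum <- function(trajectory, z_opt_new, N_anc) {
  g <- first_reach_gen(trajectory, 0.99 * z_opt_new)
  if (is.na(g)) NA_real_ else g / N_anc
}

#' Adaptation rate in z-scores per generation
#'
#' Speed of adaptation corrected for the genetic variance available at the
#' shift: the optimum displacement in units of the equilibrium genetic
#' standard deviation, divided by the number of generations needed to
#' reach the optimum.
#'
#' @param trajectory Trajectory data.frame.
#' @param V_G0 Equilibrium genetic variance at the shift (positive).
#' @param z_opt_new New optimum.
#' @param z_initial Mean trait at the shift (default 0).
#' @return z-scores per generation; `NA` if the optimum was not reached.
#' @export
adaptation_rate <- function(trajectory, V_G0, z_opt_new, z_initial = 0) {
  if (!is.numeric(V_G0) || V_G0 <= 0) stop("V_G0 must be positive")
  g <- first_reach_gen(trajectory, 0.99 * z_opt_new)
  if (is.na(g)) return(NA_real_)
  ((z_opt_new - z_initial) / sqrt(V_G0)) / g
}

#' Site frequency spectrum of segregating mutations
#'
#' Bins segregating-site frequencies into `n_bins` equal-width bins on
#' `(0, 1)` and provides the neutral reference spectrum (proportional to
#' `1/i` over derived-allele counts, scaled to the observed number of
#' segregating sites).
#'
#' @param frequencies Derived-allele frequencies of segregating sites
#'   (strictly between 0 and 1), or a snapshot list with `mutations` and
#'   `n`.
#' @param n_bins Number of frequency bins (default 20).
#' @param two_N Number of chromosomes, needed for the neutral reference;
#'   inferred from a snapshot, otherwise optional.
#' @return A data.frame with `bin_lo`, `bin_hi`, `count`, and
#'   `neutral_expected`.
#' @export
sfs <- function(frequencies, n_bins = 20, two_N = NULL) {
  if (is.list(frequencies) && !is.null(frequencies$mutations)) {
    two_N <- 2 * frequencies$n
    frequencies <- frequencies$mutations$count / two_N
  }
  frequencies <- frequencies[frequencies > 0 & frequencies < 1]
  edges <- seq(0, 1, length.out = n_bins + 1)
  if (length(frequencies) == 0L) {
    return(data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                      count = 0L, neutral_expected = 0))
  }
  idx <- findInterval(frequencies, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  neutral <- rep(NA_real_, n_bins)
  if (!is.null(two_N)) {
    i <- seq_len(two_N - 1)
    w <- 1 / i
    bin_of_i <- findInterval(i / two_N, edges, rightmost.closed = TRUE)
    neutral <- vapply(seq_len(n_bins),
                      function(b) sum(w[bin_of_i == b]), numeric(1))
    neutral <- neutral / sum(neutral) * length(frequencies)
  }
  data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
             count = counts, neutral_expected = neutral)
}

#' Fixation descriptors
#'
#' Counts and mean effect sizes of fixed mutations, overall and split by
#' effect sign. Means over an empty sign class are `NA`, not 0.
#'
#' @param fixations Fixation table with an `effect` column.
#' @return One-row data.frame: `n_fixations`, `mean_effect`,
#'   `mean_effect_pos`, `mean_effect_neg`.
#' @export
fixation_stats <- function(fixations) {
  eff <- fixations$effect
  pos <- eff[eff > 0]
  neg <- eff[eff < 0]
  data.frame(
    n_fixations = length(eff),
    mean_effect = if (length(eff)) mean(eff) else NA_real_,
    mean_effect_pos = if (length(pos)) mean(pos) else NA_real_,
    mean_effect_neg = if (length(neg)) mean(neg) else NA_real_
  )
}

#' Segregating-site descriptors
#'
#' Counts, mean frequencies and mean effects of positive- and
#' negative-effect segregating sites in a final-generation table.
#'
#' @param segregating Segregating-site table with `effect` and `frequency`.
#' @return One-row data.frame with counts, mean frequencies, mean effects
#'   and the proportion of negative sites.
#' @export
segregating_stats <- function(segregating) {
  pos <- segregating$effect > 0
  neg <- segregating$effect < 0
  n <- nrow(segregating)
  data.frame(
    n_segregating = n,
    n_pos = sum(pos), n_neg = sum(neg),
    prop_negative = if (n > 0) sum(neg) / n else NA_real_,
    mean_freq_pos = if (any(pos)) mean(segregating$frequency[pos]) else NA_real_,
    mean_freq_neg = if (any(neg)) mean(segregating$frequency[neg]) else NA_real_,
    mean_effect_pos = if (any(pos)) mean(segregating$effect[pos]) else NA_real_,
    mean_effect_neg = if (any(neg)) mean(segregating$effect[neg]) else NA_real_
  )
}

#' Summarize one adaptation replicate
#'
#' Builds the one-row summary used as input to the importance analysis:
#' the swept input parameters plus the adaptation, fixation, sweep and
#' segregating-site statistics of a single replicate.
#'
#' @param sim A `sim_result` from [run_adaptation()].
#' @param null A `neutral_null` (or threshold in generations) for sweep
#'   classification.
#' @param V_G0 Equilibrium genetic variance at the shift (e.g. the mean
#'   over the last generations of the burn-in trajectory).
#' @return A one-row data.frame (`summary_row`).
#' @export
summarize_replicate <- function(sim, null, V_G0) {
  p <- sim$params
  d <- sim$demography
  cls <- classify_fixations(sim$fixations, null)
  sw <- sweep_summary(cls, p$z_opt_new - p$z_opt_initial)
  fx <- fixation_stats(sim$fixations)
  seg <- segregating_stats(sim$segregating)
  traj <- sim$trajectory
  tto <- time_to_optimum(traj, p$z_opt_new, d$N_anc)
  rate <- if (is.na(tto)) NA_real_ else
    adaptation_rate(traj, V_G0, p$z_opt_new)
  names(seg)[-1] <- paste0("seg_", names(seg)[-1])
  cbind(
    data.frame(sigma_m = p$sigma_m, V_S = p$V_S, psi = p$psi,
               bottleneck_frac = d$bottleneck_frac,
               final_mult = d$final_mult, V_G0 = V_G0,
               time_to_optimum = tto,
               reached = !is.na(tto),
               adaptation_rate = rate,
               V_G_final = traj$var_G[nrow(traj)]),
    fx[, -1, drop = FALSE],  # n_fixations comes from the sweep summary
    sw, seg
  )
}

#' Aggregate replicate summaries per parameter set
#'
#' Means (and standard deviations of key statistics) over replicates,
#' grouped by the swept input parameters. Replicates that did not reach
#' the optimum are excluded from time/rate means but counted in
#' `n_reached` / `n_replicates`.
#'
#' @param rows Row-bound output of [summarize_replicate()].
#' @return Aggregated data.frame, one row per parameter set.
#' @export
aggregate_summaries <- function(rows) {
  key <- interaction(rows$sigma_m, rows$V_S, rows$psi,
                     rows$bottleneck_frac, rows$final_mult, drop = TRUE)
  num_cols <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                      c("sigma_m", "V_S", "psi", "bottleneck_frac",
                        "final_mult"))
  out <- lapply(split(rows, key), function(g) {
    means <- vapply(num_cols, function(cn) mean(g[[cn]], na.rm = TRUE),
                    numeric(1))
    cbind(
      g[1, c("sigma_m", "V_S", "psi", "bottleneck_frac", "final_mult")],
      as.data.frame(as.list(means)),
      data.frame(n_replicates = nrow(g), n_reached = sum(g$reached),
                 sd_time_to_optimum = stats::sd(g$time_to_optimum,
                                                na.rm = TRUE))
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
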