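# Classification of fixations as hard sweeps, sweeps from standing
# variation, or non-sweeps, by comparing sojourn times to the
# demography-matched neutral threshold.

#' Classify fixations against a neutral sojourn threshold
#'
#' A fixation is a selective sweep if its sojourn time (origin to fixation)
#' is shorter than the threshold, i.e. it fixed faster than 99% of neutral
#' alleles under the same demography. Sweeps are "hard" when the mutation
#' arose after the optimum shift (origin generation > 0) and "from standing
#' variation" when it was already segregating at the shift (origin <= 0).
#' Fixations during the burn-in (fixation generation <= 0) are excluded
#' upstream and rejected here.
#'
#' @param fixations Fixation table from [run_adaptation()] (columns
#'   `effect`, `origin`, `gen`, and optionally `p0`).
#' @param threshold_gen Sojourn threshold in generations (from
#'   [sweep_threshold()]), or a `neutral_null` object.
#' @param sojourn_from `"origin"` (default: sojourn counted from the origin
#'   generation, matching what the neutral null measures) or `"shift"`
#'   (counted from the optimum shift for standing variants; sensitivity
#'   switch).
#' @return The fixation table with `sojourn` and
#'   `classification` (`"hard_sweep"`, `"standing_sweep"`, `"non_sweep"`)
#'   columns added.
#' @export
classify_fixations <- function(fixations, threshold_gen,
                               sojourn_from = c("origin", "shift")) {
  sojourn_from <- match.arg(sojourn_from)
  if (inherits(threshold_gen, "neutral_null"))
    threshold_gen <- threshold_gen$threshold_gen
  fix <- as.data.frame(fixations)
  if (nrow(fix) > 0 && any(fix$gen <= 0))
    stop("fixations before the optimum shift must be excluded upstream")
  origin_eff <- if (sojourn_from == "shift") pmax(fix$origin, 0L) else fix$origin
  fix$sojourn <- fix$gen - origin_eff
  is_sweep <- fix$sojourn < threshold_gen
  fix$classification <- ifelse(
    !is_sweep, "non_sweep",
    ifelse(fix$origin > 0, "hard_sweep", "standing_sweep")
  )
  fix
}

#' Aggregate sweep statistics
#'
#' Counts and proportions of sweeps among fixations, split by type, plus
#' the share of the total adaptive change contributed by sweeps (summed
#' sweep effect sizes over the optimum displacement).
#'
#' @param classified Classified fixation table from [classify_fixations()].
#' @param total_trait_change Optimum displacement (`z_opt_new -
#'   z_opt_initial`); used for the sweep-contribution share. `NA` to skip.
#' @return A one-row data.frame: `n_fixations`, `n_sweeps`, `n_hard`,
#'   `n_standing`, `prop_sweeps` (sweeps / fixations), `prop_standing`
#'   (standing / sweeps), `sweep_effect_share`. Proportions are `NA` (not
#'   0) when their denominator is zero.
#' @export
sweep_summary <- function(classified, total_trait_change = NA_real_) {
  n <- nrow(classified)
  n_hard <- sum(classified$classification == "hard_sweep")
  n_standing <- sum(classified$classification == "standing_sweep")
  n_sweeps <- n_hard + n_standing
  sweep_eff <- sum(classified$effect[classified$classification != "non_sweep"])
  data.frame(
    n_fixations = n,
    n_sweeps = n_sweeps,
    n_hard = n_hard,
    n_standing = n_standing,
    prop_sweeps = if (n > 0) n_sweeps / n else NA_real_,
    prop_standing = if (n_sweeps > 0) n_standing / n_sweeps else NA_real_,
    sweep_effect_share = if (!is.na(total_trait_change) &&
                             total_trait_change != 0)
      sweep_eff / total_trait_change else NA_real_
  )
}
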