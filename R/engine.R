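# R-side driver of the compiled forward-simulation engine. A population
# state is a list with elements:
#   generation  integer label (<= 0 during burn-in; 0 = optimum shift)
#   gametes     list of 2N integer vectors of mutation row indices
#   mutations   data.frame(locus, pos, effect, origin, count) of
#               segregating mutations
#   baseline    summed effect of all fixed mutations
#   G, P        per-individual QTL genetic values and trait values

#' Create a founding population
#'
#' All individuals start mutation-free with trait value equal to the
#' (zero) baseline; variation builds up during the burn-in.
#'
#' @param n Diploid population size.
#' @param generation Generation label of the founders.
#' @return A `population_state` list.
#' @export
new_population <- function(n, generation = 0L) {
  stopifnot(n >= 2)
  structure(
    list(generation = as.integer(generation),
         gametes = rep(list(integer(0)), 2L * n),
         mutations = data.frame(locus = integer(0), pos = numeric(0),
                                effect = numeric(0), origin = integer(0),
                                count = integer(0)),
         baseline = 0,
         G = numeric(n), P = numeric(n)),
    class = "population_state"
  )
}

pop_size <- function(state) length(state$G)

as_engine_args <- function(params, layout) {
  list(z_opt = params$z_opt_initial, z_opt_new = params$z_opt_new,
       sigma_m = params$sigma_m, V_S = params$V_S, psi = params$psi,
       U = layout$U, n_loci = layout$n_loci, locus_len = layout$locus_len,
       genic_len = layout$genic_len, genic_frac = layout$genic_frac,
       xo_mean = layout$xo_mean)
}

run_engine <- function(state, schedule, regime, params, layout,
                       snapshot_gens = integer(0), track_fates = FALSE,
                       record_traj = TRUE, genotypes_in_snapshots = FALSE,
                       background_qtl_midparent = FALSE) {
  a <- as_engine_args(params, layout)
  cpp_simulate(state, as.integer(schedule), as.integer(regime),
               a$z_opt, a$z_opt_new, a$sigma_m, a$V_S, a$psi,
               a$U, a$n_loci, a$locus_len, a$genic_len, a$genic_frac,
               a$xo_mean, background_qtl_midparent,
               as.integer(snapshot_gens), track_fates, record_traj,
               genotypes_in_snapshots)
}

#' Advance a population by one (or more) generations
#'
#' Offspring counts follow `schedule`; parents are drawn with probability
#' proportional to fitness (Gaussian fitness under the stabilizing phase,
#' 0/1 truncation fitness under the truncation phase, where individuals
#' below the fitness median never reproduce). Each offspring is formed from
#' two independently drawn parents (selfing allowed) via recombined,
#' mutated gametes. Mutations reaching all `2N` copies move into the fixed
#' baseline; mutations at count 0 are dropped.
#'
#' @param state A `population_state`.
#' @param params A [trait_params()].
#' @param schedule Integer vector of offspring population sizes, one per
#'   generation to simulate.
#' @param phase `"stabilizing"` (Gaussian fitness at the initial optimum) or
#'   `"truncation"` (truncation fitness toward the new optimum).
#' @param layout A [qtl_layout()].
#' @return The advanced `population_state`.
#' @export
advance_generation <- function(state, params, schedule,
                               phase = c("stabilizing", "truncation"),
                               layout = qtl_layout()) {
  phase <- match.arg(phase)
  regime <- if (phase == "stabilizing") 0L else 2L
  res <- run_engine(state, schedule, regime, params, layout,
                    record_traj = FALSE)
  structure(res$state, class = "population_state")
}

#' Burn-in to mutation-selection-drift equilibrium
#'
#' Runs the population under Gaussian stabilizing selection at the initial
#' optimum for `generations` generations (10 `N_anc` by default), recording
#' the genetic variance every generation. The returned state is labelled
#' generation 0, the optimum shift.
#'
#' @param params A [trait_params()].
#' @param demography A [demography_model()]; only `N_anc` is used here.
#' @param layout A [qtl_layout()].
#' @param generations Burn-in length; defaults to `10 * N_anc`.
#' @return A list with `state` (equilibrium population at generation 0) and
#'   `trajectory` (per-generation mean trait, mean G, var_G, var_trait).
#' @export
run_burn_in <- function(params, demography, layout = qtl_layout(),
                        generations = 10 * demography$N_anc) {
  N <- demography$N_anc
  state <- new_population(N, generation = -as.integer(generations))
  res <- run_engine(state, schedule = rep(N, generations), regime = 0L,
                    params = params, layout = layout)
  list(state = structure(res$state, class = "population_state"),
       trajectory = res$trajectory)
}

#' Adaptation to the shifted optimum
#'
#' Starting from an equilibrium state at generation 0, applies the
#' demography schedule and runs `0.1 * N_anc` generations of adaptation:
#' truncation selection toward `z_opt_new` until the (pre-selection)
#' population mean trait first reaches it, then Gaussian stabilizing
#' selection at the new optimum. Records the per-generation trajectory,
#' full-population snapshots every 10 generations for the first 100
#' generations and every 100 thereafter, all fixations and losses (with
#' origin and fate generations and the frequency at the shift), and the
#' final-generation segregating-site table.
#'
#' @param state Equilibrium `population_state` from [run_burn_in()].
#' @param params A [trait_params()].
#' @param demography A [demography_model()].
#' @param layout A [qtl_layout()].
#' @param snapshot_gens Generations at which to snapshot; defaults to the
#'   recording cadence above.
#' @param genotypes_in_snapshots Keep per-gamete mutation lists in
#'   snapshots (for bookkeeping checks; memory-heavy for large N).
#' @param background_qtl_midparent Center the genomic background on the
#'   mid-parent QTL-only genetic value instead of the mid-parent trait
#'   value (sensitivity switch; see the methods vignette).
#' @return A `sim_result` list: `trajectory`, `snapshots`, `fixations`,
#'   `losses`, `segregating` (final-generation mutation table with
#'   frequency), `final_state`, `reached_gen` (first generation whose mean
#'   reached the new optimum, `NA` if never), `reached_99_gen` (99%
#'   criterion used by the time-to-optimum statistic), and the inputs.
#' @export
run_adaptation <- function(state, params, demography, layout = qtl_layout(),
                           snapshot_gens = NULL,
                           genotypes_in_snapshots = FALSE,
                           background_qtl_midparent = FALSE) {
  stopifnot(inherits(state, "population_state"))
  if (state$generation != 0L)
    stop("adaptation must start from a generation-0 (post-burn-in) state")
  Tg <- demography$T_adapt
  if (is.null(snapshot_gens)) snapshot_gens <- snapshot_cadence(Tg)
  snapshot_gens <- sort(unique(c(snapshot_gens, Tg)))
  res <- run_engine(state, schedule = demography$schedule, regime = 1L,
                    params = params, layout = layout,
                    snapshot_gens = snapshot_gens, track_fates = TRUE,
                    genotypes_in_snapshots = genotypes_in_snapshots,
                    background_qtl_midparent = background_qtl_midparent)
  traj <- res$trajectory
  reached99 <- time_to_optimum_gen(traj, params$z_opt_new)
  seg <- res$state$mutations
  seg$frequency <- seg$count / (2 * length(res$state$G))
  structure(
    list(trajectory = traj, snapshots = res$snapshots,
         fixations = res$fixations, losses = res$losses,
         segregating = seg,
         final_state = structure(res$state, class = "population_state"),
         reached_gen = res$reached_gen[1],
         reached_99_gen = reached99,
         params = params, demography = demography, layout = layout),
    class = "sim_result"
  )
}

#' Snapshot recording cadence
#'
#' Every 10 generations for the first 100 generations after the shift,
#' every 100 generations thereafter.
#'
#' @param T_adapt Total adaptation generations.
#' @return Integer vector of snapshot generations.
#' @export
snapshot_cadence <- function(T_adapt) {
  g <- c(if (T_adapt >= 10) seq(10, min(100, T_adapt), by = 10),
         if (T_adapt >= 200) seq(200, T_adapt, by = 100))
  as.integer(unique(c(g, T_adapt)))
}

first_reach_gen <- function(trajectory, threshold) {
  hit <- which(trajectory$mean_trait >= threshold)
  if (length(hit) == 0L) return(NA_integer_)
  trajectory$generation[hit[1]]
}

time_to_optimum_gen <- function(trajectory, z_opt_new) {
  first_reach_gen(trajectory, 0.99 * z_opt_new)
}

#' Recompute genetic values from gamete contents
#'
#' Bookkeeping check: reconstructs every individual's QTL genetic value
#' from its two gametes' mutation lists plus the fixed baseline. Effects
#' are per-copy (heterozygous) values, so a genotype contributes 0, `a` or
#' `2a` for 0, 1 or 2 copies and `G` is the plain sum over carried copies.
#' On a consistent state this equals the stored `G` exactly.
#'
#' @param state A `population_state` or a snapshot with `gametes`.
#' @return Numeric vector of recomputed genetic values.
#' @export
recompute_genetic_values <- function(state) {
  if (is.null(state$gametes))
    stop("state has no gamete lists (snapshot taken without genotypes?)")
  eff <- if (!is.null(state$mutations$slot)) {
    # snapshot: ids refer to engine slots
    e <- numeric(max(c(1L, state$mutations$slot)))
    e[state$mutations$slot] <- state$mutations$effect
    e
  } else state$mutations$effect
  n <- length(state$G)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ids <- c(state$gametes[[2 * i - 1]], state$gametes[[2 * i]])
    out[i] <- state$baseline + sum(eff[ids])
  }
  out
}

#' Tally allele counts from gamete contents
#'
#' @param state A `population_state` (or snapshot with `gametes`).
#' @return Named integer vector: tally of each mutation id over all gametes.
#' @export
tally_allele_counts <- function(state) {
  if (is.null(state$gametes)) stop("state has no gamete lists")
  ids <- unlist(state$gametes, use.names = FALSE)
  tab <- tabulate(ids, nbins = max(c(ids, nrow(state$mutations), 1L)))
  tab
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state: generation", x$generation, "|", length(x$G),
      "diploids |", nrow(x$mutations), "segregating mutations | baseline",
      format(x$baseline, digits = 4), "\n")
  invisible(x)
}

#' @export
print.sim_result <- function(x, ...) {
  Tg <- nrow(x$trajectory)
  cat("Adaptation run:", Tg, "generations | optimum",
      if (is.na(x$reached_99_gen)) "NOT reached"
      else paste("reached (99%) at generation", x$reached_99_gen),
      "\n  fixations:", nrow(x$fixations),
      "| segregating at end:", nrow(x$segregating), "\n")
  invisible(x)
}
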