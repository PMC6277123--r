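# Experiment orchestration: preset catalog, parameter grids, the
# burn-in-sharing grid runner, and plain-text outputs with a manifest.

#' Preset parameter sets
#'
#' * `single-scenario`: the focal scenario (sigma_m = 0.05, V_S = 1,
#'   psi = 0, constant population size).
#' * `maize-trait1`: small-effect mutations under strong stabilizing
#'   selection (sigma_m = 0.01, V_S = 1) with a domestication-like
#'   demography (bottleneck to 0.05 N_anc, growth to 10 N_anc).
#' * `maize-trait2`: large-effect mutations under weak stabilizing
#'   selection (sigma_m = 0.9, V_S = 50), same demography.
#'
#' @param name Preset name.
#' @param N_anc Ancestral population size (desk-scale default 1000).
#' @return List with `params` ([trait_params()]) and `demography`
#'   ([demography_model()]).
#' @export
preset <- function(name = c("single-scenario", "maize-trait1",
                            "maize-trait2"),
                   N_anc = 1000) {
  name <- match.arg(name)
  switch(name,
    "single-scenario" = list(
      name = name,
      params = trait_params(sigma_m = 0.05, V_S = 1, psi = 0),
      demography = demography_model(N_anc, bottleneck_frac = 1,
                                    final_mult = 1)),
    "maize-trait1" = list(
      name = name,
      params = trait_params(sigma_m = 0.01, V_S = 1, psi = 0),
      demography = demography_model(N_anc, bottleneck_frac = 0.05,
                                    final_mult = 10)),
    "maize-trait2" = list(
      name = name,
      params = trait_params(sigma_m = 0.9, V_S = 50, psi = 0),
      demography = demography_model(N_anc, bottleneck_frac = 0.05,
                                    final_mult = 10))
  )
}

#' List available presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  c("single-scenario", "maize-trait1", "maize-trait2")
}

#' The demography grid
#'
#' Twelve scenarios: bottleneck fraction in `{1, 0.10, 0.05, 0.01}`
#' crossed with final size multiple in `{1, 3, 10}`; instantaneous
#' bottleneck at the shift, exponential growth over `0.1 N_anc`
#' generations.
#'
#' @return Data.frame with `bottleneck_frac` and `final_mult`.
#' @export
demography_grid <- function() {
  expand.grid(bottleneck_frac = c(1, 0.10, 0.05, 0.01),
              final_mult = c(1, 3, 10))
}

#' Expand an experiment configuration into parameter sets
#'
#' Cartesian product of the trait grid (`sigma_m`, `V_S`, `psi`) with the
#' demography grid. The full study grid (5 x 5 x 4 traits x 12
#' demographies) yields 1,200 parameter sets.
#'
#' @param config Experiment configuration list (see [default_config()]).
#' @return Data.frame, one row per parameter set, with a `set_id` column.
#' @export
expand_parameter_grid <- function(config = default_config()) {
  g <- expand.grid(sigma_m = config$grid$sigma_m,
                   V_S = config$grid$V_S,
                   psi = config$grid$psi,
                   bottleneck_frac = config$grid$bottleneck_frac,
                   final_mult = config$grid$final_mult,
                   KEEP.OUT.ATTRS = FALSE)
  g$set_id <- sprintf("set%04d", seq_len(nrow(g)))
  g
}

#' Default experiment configuration
#'
#' The full trait and demography grids at desk scale (`N_anc = 1000`,
#' 3 replicates). `full_scale = TRUE` switches to the full study scale
#' (`N_anc = 10000`, 100 replicates) without touching the model.
#'
#' @param full_scale Use the full study problem sizes.
#' @return Configuration list.
#' @export
default_config <- function(full_scale = FALSE) {
  list(
    N_anc = if (full_scale) 10000 else 1000,
    replicates = if (full_scale) 100 else 3,
    n_null = if (full_scale) 10000 else 2000,
    grid = list(
      sigma_m = c(0.01, 0.05, 0.1, 0.3, 0.9),
      V_S = c(1, 5, 10, 20, 50),
      psi = c(0, 0.1, 0.5, 0.95),
      bottleneck_frac = c(1, 0.10, 0.05, 0.01),
      final_mult = c(1, 3, 10)
    )
  )
}

#' Read an experiment configuration file
#'
#' YAML key/value files with the same structure as [default_config()];
#' missing fields fall back to the defaults, and a `grid` section
#' overrides grid axes individually.
#'
#' @param path Path to a YAML configuration file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in setdiff(names(cfg), "grid")) base[[nm]] <- cfg[[nm]]
  for (nm in names(cfg$grid)) base$grid[[nm]] <- cfg$grid[[nm]]
  base
}

#' Run a (mini-)experiment over a parameter grid
#'
#' For every parameter set and replicate: burn-in (shared across all
#' parameter sets with the same `(sigma_m, V_S)` trait, as replicated
#' equilibrium populations), adaptation run, sweep classification against
#' the cached demography-matched null, and a summary row. Returns all
#' tables in memory and optionally writes them as TSV plus a JSON-style
#' manifest recording every seed.
#'
#' @param grid Parameter-set data.frame from [expand_parameter_grid()] (or
#'   a subset).
#' @param N_anc Ancestral size.
#' @param replicates Replicates per parameter set.
#' @param n_null Fixations per neutral null.
#' @param seed Master seed; every replicate's seed derives from it and is
#'   recorded in the manifest.
#' @param out_dir Output directory for TSVs, or `NULL` to skip writing.
#' @param layout A [qtl_layout()].
#' @param burn_in_gens Burn-in length; defaults to `10 * N_anc`.
#' @return List: `summaries` (replicate rows), `aggregate`,
#'   `architectures` (per-set mean matrices), `nulls`, `manifest`.
#' @export
run_experiment <- function(grid, N_anc = 1000, replicates = 3,
                           n_null = 2000, seed = 1, out_dir = NULL,
                           layout = qtl_layout(),
                           burn_in_gens = 10 * N_anc) {
  stopifnot(nrow(grid) >= 1)
  manifest <- list(N_anc = N_anc, replicates = replicates,
                   n_null = n_null, seed = seed, runs = list())

  # shared burn-ins: one set of equilibrium populations per (sigma_m, V_S)
  trait_key <- paste(grid$sigma_m, grid$V_S, sep = "_")
  burnins <- list()
  nulls <- list()
  rows <- list()
  arch <- list()
  seg_pool <- list()

  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tk <- trait_key[i]
    params <- trait_params(sigma_m = g$sigma_m, V_S = g$V_S, psi = g$psi)
    demog <- demography_model(N_anc, g$bottleneck_frac, g$final_mult)
    dk <- paste(g$bottleneck_frac, g$final_mult, sep = "_")

    if (is.null(burnins[[tk]])) {
      burnins[[tk]] <- lapply(seq_len(replicates), function(r) {
        set.seed(seed + 7919L * match(tk, unique(trait_key)) + r)
        b <- run_burn_in(trait_params(sigma_m = g$sigma_m, V_S = g$V_S),
                         demography_model(N_anc), layout,
                         generations = burn_in_gens)
        tail_window <- max(1L, nrow(b$trajectory) - 2L * N_anc + 1L)
        list(state = b$state,
             V_G0 = mean(b$trajectory$var_G[
               tail_window:nrow(b$trajectory)]))
      })
    }
    if (is.null(nulls[[dk]])) {
      demog_keys <- unique(paste(grid$bottleneck_frac, grid$final_mult,
                                 sep = "_"))
      set.seed(seed + 104729L + match(dk, demog_keys))
      nulls[[dk]] <- simulate_neutral_sojourns(demog, n_fixations = n_null,
                                               burn_in = burn_in_gens)
    }

    reps <- vector("list", replicates)
    seg_effects <- list()
    set_mats_input <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      rep_seed <- as.integer((seed + 7919 * i + 1299709 * r) %% 2147483647)
      set.seed(rep_seed)
      sim <- run_adaptation(burnins[[tk]][[r]]$state, params, demog, layout)
      reps[[r]] <- summarize_replicate(sim, nulls[[dk]],
                                       burnins[[tk]][[r]]$V_G0)
      reps[[r]]$set_id <- g$set_id
      reps[[r]]$replicate <- r
      seg_effects[[r]] <- sim$segregating$effect
      set_mats_input[[r]] <- sim$segregating[, c("frequency", "effect")]
      manifest$runs[[length(manifest$runs) + 1L]] <-
        list(set_id = g$set_id, replicate = r, seed = rep_seed)
    }
    pooled <- unlist(seg_effects)
    mats <- NULL
    if (length(unique(pooled)) >= 9) {
      edges <- effect_bin_edges(pooled)
      mats <- lapply(set_mats_input, build_architecture_matrix,
                     edges = edges)
      arch[[g$set_id]] <- mean_architecture(mats)
    }
    rows[[i]] <- do.call(rbind, reps)
    seg_pool[[g$set_id]] <- pooled
  }

  summaries <- do.call(rbind, rows)
  agg <- aggregate_summaries(summaries)

  result <- list(summaries = summaries, aggregate = agg,
                 architectures = arch, nulls = nulls, manifest = manifest)
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' Write experiment outputs as plain text
#'
#' `summary.tsv` (one row per replicate), `aggregate.tsv` (per parameter
#' set), `architecture.tsv` (63 labeled cells per set), `null.tsv`
#' (sojourn times per demography) and `manifest.json`.
#'
#' @param result Output of [run_experiment()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(d, f)
    utils::write.table(d, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv(result$summaries, "summary.tsv")
  write_tsv(result$aggregate, "aggregate.tsv")
  if (length(result$architectures) > 0) {
    cells <- do.call(rbind, lapply(names(result$architectures), function(id) {
      m <- result$architectures[[id]]
      data.frame(set_id = id,
                 freq_bin = rep(rownames(m), ncol(m)),
                 effect_bin = rep(colnames(m), each = nrow(m)),
                 frequency = as.vector(unclass(m)))
    }))
    write_tsv(cells, "architecture.tsv")
  }
  nulltab <- do.call(rbind, lapply(names(result$nulls), function(id)
    data.frame(demography = id, sojourn = result$nulls[[id]]$sojourns)))
  write_tsv(nulltab, "null.tsv")
  manifest_json <- paste0(
    '{"N_anc": ', result$manifest$N_anc,
    ', "replicates": ', result$manifest$replicates,
    ', "seed": ', result$manifest$seed,
    ', "runs": [',
    paste(vapply(result$manifest$runs, function(r)
      sprintf('{"set_id": "%s", "replicate": %d, "seed": %d}',
              r$set_id, r$replicate, r$seed), character(1)),
      collapse = ", "),
    ']}')
  writeLines(manifest_json, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
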