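#!/usr/bin/env Rscript
# Stage 2: a desk-scale sweep over the trait and demography grids.
# Runs a reduced Cartesian grid (the full study grid of 1,200
# parameter sets is expanded but subsampled here; pass --full to run all
# of it overnight), producing per-replicate summary rows, per-set
# aggregates, and cached neutral nulls, all under results/grid/.

library(polyadapt)

full <- "--full" %in% commandArgs(trailingOnly = TRUE)
N_anc <- 500
out <- "results/grid"
set.seed(202)

if (full) {
  grid <- expand_parameter_grid(default_config())
  replicates <- 10
} else {
  grid <- expand_parameter_grid(list(grid = list(
    sigma_m = c(0.01, 0.05, 0.1, 0.3, 0.9),
    V_S = c(1, 10, 50),
    psi = c(0, 0.5),
    bottleneck_frac = c(1, 0.05),
    final_mult = c(1, 10))))
  replicates <- 3
}
message(nrow(grid), " parameter sets x ", replicates, " replicates at N_anc = ",
        N_anc)

res <- run_experiment(grid, N_anc = N_anc, replicates = replicates,
                      n_null = 2000, seed = 203, out_dir = out)

agg <- res$aggregate
message(sprintf("%d/%d parameter sets reached the optimum in every replicate",
                sum(agg$n_reached == agg$n_replicates), nrow(agg)))
message(sprintf("fastest adaptation: sigma_m=%g V_S=%g psi=%g (%.4f N_anc)",
                agg$sigma_m[which.min(agg$time_to_optimum)],
                agg$V_S[which.min(agg$time_to_optimum)],
                agg$psi[which.min(agg$time_to_optimum)],
                min(agg$time_to_optimum, na.rm = TRUE)))
message("wrote ", out)
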