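#!/usr/bin/env Rscript
# Stage 1: detailed look at one focal scenario -- a constant-size
# population with intermediate effect sizes (sigma_m = 0.05), strong
# stabilizing selection (V_S = 1) and no genomic background, adapting to
# an optimum shift from 0 to 10.
#
# Writes: results/single/trajectory.tsv, fixations.tsv, segregating.tsv,
#         sfs_by_stage.tsv, sweep_summary.tsv
#
# Desk scale (N_anc = 2000, minutes). The full-scale equivalent is in
# analysis/05_full_scale.R.

library(polyadapt)

N_anc <- 2000
n_reps <- 5
out <- "results/single"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(101)

pr <- preset("single-scenario", N_anc = N_anc)
message("burn-in (10N generations) ...")
b <- run_burn_in(pr$params, pr$demography)
V_G0 <- mean(tail(b$trajectory$var_G, 2 * N_anc))
message(sprintf("  V_G0 = %.5f  (stochastic HoC expectation %.5f)",
                V_G0, stochastic_hoc_expectation(3e-3, 1, N_anc, 0.05)))
message(sprintf("  optimum shift = %.1f z-scores of sqrt(V_G0)",
                10 / sqrt(V_G0)))

null <- simulate_neutral_sojourns(pr$demography, n_fixations = 10000)
message(sprintf("neutral null: mean sojourn %.0f gens, 1%% threshold %.0f",
                mean(null$sojourns), null$threshold_gen))

traj_all <- NULL
fix_all <- NULL
sfs_all <- NULL
sw_all <- NULL
for (r in seq_len(n_reps)) {
  sim <- run_adaptation(b$state, pr$params, pr$demography)
  tr <- sim$trajectory
  tr$replicate <- r
  traj_all <- rbind(traj_all, tr)
  cls <- classify_fixations(sim$fixations, null)
  cls$replicate <- r
  fix_all <- rbind(fix_all, cls)
  sw <- sweep_summary(cls, 10)
  sw$replicate <- r
  sw$time_to_optimum <- time_to_optimum(tr, 10, N_anc)
  sw_all <- rbind(sw_all, sw)
  # SFS at the recorded stages (before/after optimum, final)
  for (sn in sim$snapshots) {
    s <- sfs(sn, n_bins = 20)
    s$generation <- sn$generation
    s$replicate <- r
    sfs_all <- rbind(sfs_all, s)
  }
  if (r == 1) {
    write.table(sim$segregating, file.path(out, "segregating.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

write.table(traj_all, file.path(out, "trajectory.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fix_all, file.path(out, "fixations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sfs_all, file.path(out, "sfs_by_stage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sw_all, file.path(out, "sweep_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "over %d replicates: time to optimum %.4f N_anc (%.0f generations); %.0f%% of fixations were sweeps, %.0f%% of sweeps from standing variation",
  n_reps, mean(sw_all$time_to_optimum, na.rm = TRUE),
  mean(sw_all$time_to_optimum, na.rm = TRUE) * N_anc,
  100 * mean(sw_all$prop_sweeps, na.rm = TRUE),
  100 * mean(sw_all$prop_standing, na.rm = TRUE)))
message("wrote ", out)
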