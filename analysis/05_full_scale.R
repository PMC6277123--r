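#!/usr/bin/env Rscript
# Stage 5 (overnight): the headline statistics at the full study problem
# size -- N_anc = 10,000, burn-in 100,000 generations, adaptation window
# 1,000 generations. A single burn-in at this size takes on the order of
# half an hour on one core; the full stage (focal scenario + both maize
# presets, 10 replicates each) runs for several hours. Results land in
# results/full_scale/ in the same formats as stages 1 and 4.

library(polyadapt)

N_anc <- 10000
n_reps <- 10
out <- "results/full_scale"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(505)

scenarios <- c("single-scenario", "maize-trait1", "maize-trait2")
rows <- NULL
arch <- list()
for (pn in scenarios) {
  pr <- preset(pn, N_anc = N_anc)
  message(pn, ": burn-in (this is the slow part) ...")
  b <- run_burn_in(pr$params, demography_model(N_anc))
  V_G0 <- mean(tail(b$trajectory$var_G, 2 * N_anc))
  null <- simulate_neutral_sojourns(pr$demography, n_fixations = 10000)
  sims <- lapply(seq_len(n_reps), function(r)
    run_adaptation(b$state, pr$params, pr$demography))
  fx <- do.call(rbind, lapply(sims, function(s)
    classify_fixations(s$fixations, null)))
  sw <- sweep_summary(fx, 10)
  tto <- vapply(sims, function(s) as.numeric(s$reached_99_gen), numeric(1))
  sw$scenario <- pn
  sw$V_G0 <- V_G0
  sw$z_distance <- 10 / sqrt(V_G0)
  sw$time_to_optimum_Nanc <- mean(tto, na.rm = TRUE) / N_anc
  sw$vg_min_gen_Nanc <- mean(vapply(sims, function(s)
    s$trajectory$generation[which.min(s$trajectory$var_G)],
    numeric(1))) / N_anc
  rows <- rbind(rows, sw)
  pooled <- unlist(lapply(sims, function(s) s$segregating$effect))
  arch[[pn]] <- mean_architecture(lapply(sims, function(s)
    build_architecture_matrix(s$segregating, effect_bin_edges(pooled))))
  message(sprintf(
    "  time to optimum %.4f N_anc | sweeps/fixations %.2f | standing/sweeps %.2f",
    sw$time_to_optimum_Nanc, sw$prop_sweeps, sw$prop_standing))
}
write.table(rows, file.path(out, "headline_statistics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("maize architecture correlation: %.3f",
                matrix_correlation(arch[["maize-trait1"]],
                                   arch[["maize-trait2"]])))
message("wrote ", out)
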