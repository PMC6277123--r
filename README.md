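# polyadapt

Forward-time simulation and analysis of **polygenic adaptation to a distant
trait optimum**.

When the environment shifts suddenly, a quantitative trait adapts through
allele-frequency changes at many loci at once — some of which fix so fast
they constitute selective sweeps. How the speed of adaptation, the mix of
hard sweeps versus sweeps from standing variation, and the final genetic
architecture of the trait depend on the trait's genetics and the
population's demography is the question this package addresses. It is
aimed at population and quantitative geneticists who want a controlled,
reproducible sandbox for these dynamics.

## The model

A diploid, randomly mating population carries 20 unlinked 50 kb QTL
regions (4 kb genic cores; per-gamete trait mutation rate `U = 3e-3`,
within-region recombination `5e-8`/bp). Mutation effects are additive,
drawn from `Normal(0, σ_m²)` per copy. Under stabilizing selection an
individual of trait value *z* has fitness

```
w = exp( −(z − z_opt)² / (2 V_S) )
```

After a burn-in of `10 N_anc` generations at the old optimum (0), the
optimum jumps to 10 and the population undergoes **truncation selection**
(fitness 1 for the top half ranked by *w*, 0 otherwise) until its mean
reaches the new optimum, then returns to stabilizing selection — while a
configurable bottleneck-and-growth demography and a heritable genomic
background (weight `ψ`) run underneath. Equilibrium genetic variance
follows the stochastic house-of-cards approximation
`4UV_S / (1 + V_S/(N σ_m²))`.

Fixations are classified against a demography-matched neutral null
(single-locus binomial sampling of sojourn times): any mutation fixing
faster than 99% of neutral alleles is a sweep — *hard* if it arose after
the shift, *from standing variation* otherwise. Final-generation
populations are summarized into 7 (frequency) × 9 (effect quantile)
genetic-architecture matrices, and random-forest regressions extract how
much each input parameter (`σ_m`, `V_S`, `ψ`, bottleneck, growth)
determines each outcome.

## A worked example

A large-effect trait under weak stabilizing selection (`σ_m = 0.9`,
`V_S = 50`) adapting through a domestication-style bottleneck:

```r
library(polyadapt)
set.seed(42)

pr <- preset("maize-trait2", N_anc = 1000)
eq <- run_burn_in(pr$params, demography_model(1000))
V_G0 <- mean(tail(eq$trajectory$var_G, 2000))
cat(sprintf("equilibrium V_G = %.3f (stochastic HoC expectation %.3f)\n",
            V_G0, stochastic_hoc_expectation(3e-3, 50, 1000, 0.9)))

sim <- run_adaptation(eq$state, pr$params, pr$demography)
print(sim)

null <- simulate_neutral_sojourns(pr$demography, n_fixations = 2000)
print(null)

fx <- classify_fixations(sim$fixations, null)
print(sweep_summary(fx, total_trait_change = 10))
```

```
equilibrium V_G = 0.577 (stochastic HoC expectation 0.565)
Adaptation run: 100 generations | optimum reached (99%) at generation 13 
  fixations: 3 | segregating at end: 321 
Neutral null: 2000 conditional fixation times | mean sojourn 3680.2 generations |  1 % threshold 1016 
  n_fixations n_sweeps n_hard n_standing prop_sweeps prop_standing
1           3        3      0          3           1             1
  sweep_effect_share
1          0.3550917
```

Read: the trait sits on abundant standing variation (`V_G ≈ 0.58`,
matching the closed-form expectation), so it reaches the new optimum in
just 13 generations; only 3 mutations fix, all faster than the neutral 1%
threshold (1016 generations), all from standing variation, and together
their fixation accounts for ~36% of the 10-unit trait change. Contrast
`preset("maize-trait1")` — small effects, strong selection — which fixes
hundreds of mutations, mostly as hard sweeps, and adapts an order of
magnitude more slowly.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the study's stages at desk
scale, writing TSVs under `results/`:

1. `01_single_scenario.R` — trajectories, SFS, fixation timing and sweep
   summaries for the focal scenario (`σ_m = 0.05`, `V_S = 1`, constant N).
2. `02_parameter_grid.R` — the trait × demography grid (`--full` expands
   all 1,200 parameter sets of the full study grid).
3. `03_importance.R` — random-forest importances, 10-fold CV accuracy and
   NRMSD for every summary statistic.
4. `04_maize_traits.R` — the two contrasting domestication presets and
   their architecture-matrix correlation.
5. `05_full_scale.R` — the overnight, full-scale run
   (`N_anc = 10,000`).

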