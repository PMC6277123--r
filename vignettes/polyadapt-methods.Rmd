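---
title: "Simulating polygenic adaptation to a distant trait optimum: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating polygenic adaptation to a distant trait optimum: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyadapt is an individual-based forward-time simulator for a single
quantitative trait adapting to a sudden environmental change, together with
the machinery needed to analyze the outcome: a demography-matched neutral
null for calling selective sweeps, summary statistics of the adaptive
process, genetic-architecture matrices, and random-forest parameter
importance. This vignette describes the model, the numerical choices, and
what the package's tests do and do not establish.

## The model

A diploid population of `N` randomly mating individuals carries 20 unlinked
QTL regions, each 50 kb with a 4 kb genic core. Trait-affecting mutations
arise at a total rate of `U = 3e-3` per gamete per generation, fall on a
region uniformly and inside it on the genic core with probability
`4000 / (4000 + 0.01 * 46000) ~ 0.897` (intergenic sites mutate at 1% of
the genic per-site rate), at continuous coordinates: the
infinitely-many-sites assumption, so there is no recurrent or back
mutation. Within a region, crossovers arrive at `5e-8` per bp per
generation (0.05 per gamete in total); regions assort freely.

The model is purely additive, with no dominance or epistasis. Each
mutation's stored effect size `a` is drawn from `Normal(0, sigma_m^2)` and
is the **per-copy (heterozygous) effect**: a genotype contributes `0`, `a`
or `2a` to the genetic value `G` for 0, 1 or 2 copies. We adopted this
convention -- rather than treating the drawn value as the homozygous
difference -- because it is the one under which the realized equilibrium
genetic variance matches the stochastic house-of-cards expectation written
in terms of `sigma_m` (below), and under which the optimum displacement of
the focal scenario corresponds to the ~90 phenotypic standard deviations
that motivate the truncation-selection regime. Fixed mutations leave the
segregating table and fold their homozygous effect `2a` into a scalar
baseline carried by every individual.

### Fitness and the two selection regimes

Under stabilizing selection an individual of trait value `z` has fitness

    w = exp( -(z - z_opt)^2 / (2 * V_S) )

with larger `V_S` meaning weaker selection. During adaptation to the
shifted optimum (0 to 10 by default) this Gaussian form would hand nearly
all reproduction to a few tail individuals, so the adaptation phase uses
truncation selection instead: fitness 1 for the top `ceiling(n/2)`
individuals ranked by `w` (ties broken by stable index order -- a
deterministic, testable rule) and 0 for the rest. Truncation ends
permanently at the first generation whose pre-selection population mean
reaches the new optimum; stabilizing selection around the new optimum then
resumes. The pre-selection mean is the natural place to test the exit
condition because it is the quantity that exists before fitnesses are
assigned; the alternative (testing after reproduction) shifts the exit by
at most one generation. If the "new" optimum equals the old one, no
truncation phase is ever triggered. The separate *time to optimum*
statistic uses the first generation whose mean reaches 99% of the new
optimum, in units of `N_anc` generations.

Parents are drawn independently with replacement, with probability
proportional to fitness (uniformly among survivors under truncation);
selfing is allowed, the standard Wright-Fisher convention.

### The heritable genomic background

Simulating a whole genome is not feasible, so the rest of the genome enters
as a heritable background value

    G_B ~ Normal(G_mp, sigma2_parental),    P = psi * G_B + (1 - psi) * G

where `psi` in `[0, 1]` weights the background against the explicit QTL.
Two readings of "mid-parent value" are possible. We center `G_B` on the
mid-parent **trait** value `(P_1 + P_2) / 2`: because the phenotype here
has no environmental component, an individual's trait value *is* its total
genotypic value, and only this reading makes the background heritable --
with a QTL-only mid-parent the background would regress to the QTL mean
every generation and populations with `psi = 0.95` could barely adapt,
the opposite of what large-background populations do (they adapt fastest).
The QTL-only centering is available as a sensitivity switch
(`background_qtl_midparent = TRUE` in `run_adaptation()`).
`sigma2_parental` is the population variance of the parental generation's
trait values, recomputed every generation; per-mating-pair alternatives are
not well defined by "the variance of the parental trait values" and are
not implemented. During burn-in the equilibrium depends only on
`(sigma_m, V_S)`; equilibrium populations are generated with `psi = 0` and
shared across all background levels, which is also what makes burn-in
sharing across the grid coherent.

### Demography

The burn-in runs at constant `N_anc` for `10 * N_anc` generations, long
enough for the mean fitness and `V_G` to stabilize. At generation 0 (the
optimum shift) the size drops instantaneously to
`bottleneck_frac * N_anc` and grows exponentially to
`final_mult * N_anc` over the `0.1 * N_anc`-generation adaptation window:
`N(t) = N_b * (N_f / N_b)^(t / T)` rounded to the nearest integer. The
grid of 12 demographies crosses `bottleneck_frac` in {1, 0.10, 0.05, 0.01}
with `final_mult` in {1, 3, 10}.

## Equilibrium genetic variance

At mutation-selection balance the house-of-cards approximation gives
`E[V_G] = 4 U V_S`, independent of the effect-size scale; the stochastic
house of cards adds the finite-population correction

    E[V_G] = 4 U V_S / (1 + V_S / (N sigma_m^2)).

The suite verifies that time-averaged `V_G` over the last `5N` burn-in
generations, averaged over 12 replicate burn-ins, sits within 15% of this
expression across a 3x3 grid (`sigma_m` in {0.05, 0.1, 0.3}, `V_S` in
{1, 5, 10}) at `N = 500`. Replicate averaging matters: `V_G` at
equilibrium is dominated by a handful of intermediate-frequency sites and
has an autocorrelation time of order `N`, so a single window average can
deviate by 30% or more without indicating any model error.

## The neutral null and sweep classification

A fixation counts as a selective sweep when it fixed faster than 99% of
neutral alleles experiencing the same demography. The null is built by
single-locus binomial sampling: single-copy mutations injected at uniform
origin times over burn-in plus adaptation window, propagated as
`x' ~ Binomial(2N', x / 2N)`, keeping the origin-to-fixation times of
mutations that fix inside the final `0.1 * N_anc` window (mutations lost,
fixed earlier, or still segregating are ignored). Because a neutral
allele's frequency is a martingale, its fixation probability from count
`x` is exactly `x / 2N` under any demography, and the chain conditioned on
eventual fixation has the size-biased transition
`x' = 1 + Binomial(2N' - 1, x / 2N)`. The default sampler simulates this
conditioned chain -- every trajectory fixes -- and is distributionally
identical to naive rejection, which is retained as `method = "binomial"`
and compared against the default by a KS test in the suite. For constant
demographies the fix-in-window restriction leaves the sojourn law
unchanged (origins are uniform over a span much longer than the window),
so the window rejection is skipped there. The threshold is the 1st
percentile of the collected sojourns, with linear interpolation between
order statistics (`quantile()` type 7); the percentile method is
config-overridable.

Classification is by the same origin-anchored sojourn the null measures:
`fixation_generation - origin_generation`, sweeps split into *hard*
(origin after the shift) and *from standing variation* (origin at or
before the shift). Anchoring standing variants' sojourns at the shift
instead is offered as a sensitivity switch but not the default: it is
inconsistent with what the null measures, and empirically it classifies
essentially every post-shift fixation as a sweep, which contradicts the
~72% sweep fraction the focal scenario should produce. Replicates report
both per-replicate and pooled proportions; fixations from the burn-in are
excluded throughout.

## Genetic-architecture matrices

The architecture of a final-generation population is the joint relative
occurrence of its segregating sites over 7 allele-frequency bins
(0-1e-4, 1e-4-1e-3, 1e-3-1e-2, 1e-2-0.1, 0.1-0.5, 0.5-0.9, 0.9-1;
half-open on the right, sites at exactly 0 or 1 excluded as
non-segregating) and 9 effect-size bins, normalized to sum to 1. Effect
bins are quantile-based because absolute effects scale with `sigma_m`:
the central bin spans `(-q, +q)` with `q` the 1/9 quantile of the pooled
absolute effects -- chosen so the nine bins have roughly equal occupancy
on a symmetric effect distribution, the most direct reading of "nine
quantile bins centered on zero" -- and each side is split into four
equal-count quantile bins. Edges are computed from effects pooled across
all replicates of one parameter set, making replicate matrices
comparable; the per-parameter-set matrix is the renormalized mean of
replicate matrices. Matrix comparisons are Pearson correlations over the
63 cells, undefined (reported missing) for zero-variance matrices.

## Parameter importance

Each summary statistic (and each architecture cell) is predicted from the
five swept inputs -- `sigma_m`, `V_S` (or the realized `V_G0`), `psi`,
bottleneck fraction, final-size multiple -- by a 100-tree random forest
(randomForest, impurity importance, `mtry` = all features to mirror the
reference regressor's defaults), importances normalized to sum to 1.
Accuracy is 10-fold cross validation with per-fold refits ("nested" is
read as plain k-fold: there is no hyperparameter search to nest over);
out-of-fold predictions are pooled into an R^2 and an NRMSD
(RMSE / target range). NRMSD is always reported because R^2 is misleading
for targets concentrated near zero, such as mean segregating effect
sizes. Architecture importance fits one forest per non-constant cell and
averages the normalized per-cell importances. Impurity importances are
biased toward features with more split points, which is why the suite's
noise-feature check uses a discrete noise feature comparable to the real
(discrete) parameters.

## Problem sizes, reproducibility, and what the tests show

Every stochastic component draws from R's RNG (the compiled engine seeds
an internal xoshiro256++ generator from it), so `(configuration, seed)`
reproduces every table byte-identically; the experiment runner records
each replicate's seed in a manifest.

The full study scale -- `N_anc = 10,000`, a 100,000-generation
burn-in, 100 replicates per parameter set, 1,200 parameter sets -- is
supported by configuration but is an overnight job
(`analysis/05_full_scale.R`). The suite and the bundled analyses use
reduced sizes chosen so each stage finishes in minutes: equilibrium
checks at `N = 500`, the focal scenario at `N_anc = 5000` (tests) or 4000
(acceptance script), the maize presets at `N_anc = 2000`, and the
importance grid at `N_anc = 400-500`.

Scale changes what some statistics mean. Quantities set by selection on
the available variance -- the time to optimum in *absolute* generations
(~110 for the focal trait, ~20 for maize Trait 2), the sweep fraction
among fixations, the shape of the architecture matrix -- are nearly
scale-free and are checked against their full-scale values directly.
Quantities tied to the mutational input `2NU` or to the `0.1 N_anc`
window -- fixation and sweep *counts*, the standing-variation share of
sweeps (standing variation scales with `N`), times expressed in `N_anc`
units, the timing of the Trait 1 variance minimum -- shift predictably
with `N_anc`; the suite checks those as ratios or with bands that reflect
the reduced standing variation, and the desk-scale focal preset
(`N_anc = 1000`) cannot reach the optimum inside its 100-generation
window at all (its expected time, ~130 absolute generations, hardly
shrinks with `N`), which is why the scaled-down checks run at
`N_anc >= 2000`.

What passing tests establish is internal consistency (exact bookkeeping of
genetic values and allele counts, exact partitions and normalizations,
determinism) and agreement with independent oracles (binomial
Wright-Fisher dynamics, diffusion-theory fixation times, the stochastic
house of cards, chi-squared agreement of the neutral-reduction SFS with a
single-locus oracle). They do not establish that real traits behave like
this model: there are no linked neutral sites, no dominance or epistasis,
one trait with full heritability aside from the modeled background, and a
single instantaneous optimum shift.

## Known limitations

* No linked neutral variation, so sweeps are defined by fixation speed,
  not by diversity signatures.
* The truncation exit tests the pre-selection mean; populations
  fluctuating around the optimum re-enter stabilizing selection
  permanently, never a second truncation episode.
* `V_G` is recorded as the population variance of individual `G` values
  (denominator `n`), which includes linkage-disequilibrium contributions;
  at linkage equilibrium it coincides with the additive-variance formula.
* The neutral-null fast path at constant `N` ignores the (negligible)
  truncation of sojourns longer than the whole simulated span.
* Architecture-matrix effect-bin edges require at least 9 distinct pooled
  effect sizes; parameter sets with fewer segregating sites report no
  matrix rather than a degenerate one.
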