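// Single-locus binomial (Wright-Fisher) sampling of neutral allele
// trajectories under an arbitrary diploid-size schedule, used to build the
// demography-matched null distribution of conditional fixation (sojourn)
// times. Two samplers:
//
//  * naive: inject a single copy, propagate x' ~ Binom(2N', x/2N), keep the
//    sojourn only if the allele fixes inside the acceptance window. This is
//    the scheme as usually described; almost all injections are lost.
//
//  * conditioned: exact h-transform of the same chain. For a neutral allele
//    the frequency is a martingale, so under any demography the fixation
//    probability from count x is x/2N; the chain conditioned on eventual
//    fixation has the size-biased binomial transition
//    x' = 1 + Binom(2N' - 1, x/2N). Every trajectory fixes, giving the same
//    sojourn law at a fraction of the cost.
//
// Both use R's RNG (set.seed() applies).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// schedule[t] = diploid size of generation t+1 (offspring of generation t);
// sizes are constant N over a burn-in handled by the caller via the
// schedule itself. Origins are drawn uniformly on 0..(T-1) (the generation
// whose offspring first carry the allele is origin+1). A sojourn is
// accepted iff fixation happens at generation > window_start and <= T.
//
// Returns sojourn times (generations from origin to fixation).

// [[Rcpp::export]]
NumericVector cpp_neutral_sojourns(IntegerVector schedule, int n_fixations,
                                   int window_start, bool conditioned,
                                   double max_tries) {
  int T = schedule.size();
  std::vector<double> out;
  out.reserve(n_fixations);
  double tries = 0;

  while ((int)out.size() < n_fixations) {
    tries += 1;
    if (tries > max_tries)
      stop("neutral sojourn sampling exceeded max_tries before collecting "
           "the requested number of fixations");
    // origin generation: allele exists as 1 copy in generation t0's pool
    int t0 = (int)(unif_rand() * T);
    if (t0 >= T) t0 = T - 1;
    long x = 1;
    long twoN = 2L * schedule[t0];
    bool fixed = false;
    int t_fix = -1;
    for (int t = t0 + 1; t < T; t++) {
      long twoN_next = 2L * schedule[t];
      double p = (double)x / (double)twoN;
      if (conditioned) {
        x = 1 + (long)R::rbinom((double)(twoN_next - 1), p);
      } else {
        x = (long)R::rbinom((double)twoN_next, p);
        if (x == 0) break;  // lost
      }
      twoN = twoN_next;
      if (x == twoN) { fixed = true; t_fix = t + 1; break; }
    }
    // generation labels: schedule index t corresponds to generation t+1
    // sojourn: allele arises in generation t0 + 1, fixes in generation t_fix
    if (fixed && t_fix > window_start) out.push_back(t_fix - (t0 + 1));
    if (((long)tries & 1023L) == 0) Rcpp::checkUserInterrupt();
  }
  return wrap(out);
}

// Constant-N fast path: for a constant schedule the sojourn law of
// fixations landing in any fixed window equals the unconditional
// origin-free law (origins uniform over a span much longer than the
// window), so no window rejection is needed. Conditioned sampler only.

// [[Rcpp::export]]
NumericVector cpp_neutral_sojourns_constN(int N, int n_fixations,
                                          int max_generations) {
  std::vector<double> out;
  out.reserve(n_fixations);
  long twoN = 2L * N;
  while ((int)out.size() < n_fixations) {
    long x = 1;
    int t = 0;
    while (t < max_generations) {
      t++;
      x = 1 + (long)R::rbinom((double)(twoN - 1), (double)x / (double)twoN);
      if (x == twoN) break;
    }
    if (x == twoN) out.push_back(t);
    Rcpp::checkUserInterrupt();
  }
  return wrap(out);
}
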