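// Individual-based forward simulation of a diploid quantitative trait:
// unlinked QTL regions, infinitely-many-sites mutation on continuous
// coordinates, Gaussian stabilizing selection, and truncation selection
// toward a shifted optimum. The per-generation loop lives here; all policy
// (parameter values, schedules, phases) is passed in from R.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// Internal PRNG: xoshiro256++ seeded from R's RNG stream, so that set.seed()
// in R fully determines every draw made here, without unif_rand() call
// overhead in the hot loop.
struct Xoshiro {
  uint64_t s[4];
  double spare_normal = 0.0;
  bool has_spare = false;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed_from_R() {
    uint64_t x = (uint64_t)(unif_rand() * 4294967296.0);
    x = (x << 32) ^ (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline int unif_int(int n) { return (int)(unif() * n); }
  inline double normal() {  // Box-Muller with spare
    if (has_spare) { has_spare = false; return spare_normal; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare_normal = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  // inversion with precomputed exp(-lambda); lambdas here are small, so
  // the common case is a single uniform draw and one comparison
  inline int poisson(double lambda, double exp_neg_lambda) {
    double p = unif();
    if (p <= exp_neg_lambda) return 0;
    int k = 0;
    double term = exp_neg_lambda, cum = term;
    while (p > cum && k < 1000) {
      k++;
      term *= lambda / k;
      cum += term;
    }
    return k;
  }
};

// Mutation table with slot recycling: lost mutations free their slot so the
// table stays near the segregating-site count over a 10N-generation burn-in.
// gkey is a strictly ordering-preserving scalar (locus, pos) key used for
// cheap merge comparisons during meiosis.
struct MutTable {
  std::vector<int> locus;       // 0-based
  std::vector<double> pos;      // bp, continuous within locus
  std::vector<double> gkey;     // locus * (locus_len + 1) + pos
  std::vector<double> effect;   // per-copy (heterozygous) effect
  std::vector<int> origin;      // generation label (<= 0 during burn-in)
  std::vector<int> count;       // copies among current 2N gametes
  std::vector<char> active;
  std::vector<int> free_slots;
  std::vector<int> active_list;
  double key_span = 0.0;        // locus_len + 1

  int alloc(int loc, double p, double eff, int orig) {
    int slot;
    double k = loc * key_span + p;
    if (!free_slots.empty()) {
      slot = free_slots.back();
      free_slots.pop_back();
      locus[slot] = loc; pos[slot] = p; gkey[slot] = k; effect[slot] = eff;
      origin[slot] = orig; count[slot] = 0; active[slot] = 1;
    } else {
      slot = (int)locus.size();
      locus.push_back(loc); pos.push_back(p); gkey.push_back(k);
      effect.push_back(eff);
      origin.push_back(orig); count.push_back(0); active.push_back(1);
    }
    active_list.push_back(slot);
    return slot;
  }
  void release(int slot) {
    active[slot] = 0;
    free_slots.push_back(slot);
  }
};

struct FateLog {
  std::vector<int> locus, origin, gen;
  std::vector<double> pos, effect, p0;
  void add(const MutTable &tab, int slot, int g, double freq0) {
    locus.push_back(tab.locus[slot]); pos.push_back(tab.pos[slot]);
    effect.push_back(tab.effect[slot]); origin.push_back(tab.origin[slot]);
    gen.push_back(g); p0.push_back(freq0);
  }
};

struct Pop {
  int gen = 0;
  int n = 0;                               // diploids
  std::vector<std::vector<int>> gam;       // 2n gametes, sorted (locus,pos)
  MutTable tab;
  double baseline = 0.0;                   // summed effects of fixed sites
  std::vector<double> G, P;
};

struct Layout {
  int n_loci;
  double locus_len, genic_len, genic_frac;
  double U;         // per-gamete trait mutation rate
  double xo_mean;   // per-gamete crossover mean
  double p0_U;      // exp(-U)
  double p0_xo;     // exp(-xo_mean)
};

inline bool mut_before(const MutTable &tab, int a, int b) {
  return tab.gkey[a] < tab.gkey[b];
}

// Build one recombined, mutated gamete from parent `par` into `out`.
// Increments tab.count for every id placed and accumulates the per-copy
// effect sum. The common case (no crossover anywhere in the meiosis) is a
// merge walk over the two parental gametes that touches only actual
// mutations: each mutation is kept iff its locus' coin bit selects the
// gamete it sits on (free recombination between loci).
void meiosis(const Pop &pop, int par, const Layout &lay, double sigma_m,
             Xoshiro &rng, MutTable &tab, int gen_label,
             std::vector<int> &out, double &eff_sum,
             std::vector<int> &xo_per_locus, std::vector<double> &xo_pos) {
  out.clear();
  const std::vector<int> &g1 = pop.gam[2 * par];
  const std::vector<int> &g2 = pop.gam[2 * par + 1];

  int n_xo = rng.poisson(lay.xo_mean, lay.p0_xo);
  uint64_t coins = rng.next();  // one bit per locus: take gamete 1 iff set

  if (n_xo == 0) {
    const size_t e1 = g1.size(), e2 = g2.size();
    size_t i1 = 0, i2 = 0;
    while (i1 < e1 || i2 < e2) {
      bool take1;
      if (i1 >= e1) take1 = false;
      else if (i2 >= e2) take1 = true;
      else take1 = tab.gkey[g1[i1]] <= tab.gkey[g2[i2]];
      int id = take1 ? g1[i1++] : g2[i2++];
      bool from_first = ((coins >> tab.locus[id]) & 1ULL) != 0;
      if (from_first == take1) {
        out.push_back(id);
        tab.count[id]++;
        eff_sum += tab.effect[id];
      }
    }
  } else {
    // crossover path: per-locus segment walk with breakpoints
    xo_per_locus.assign(lay.n_loci, 0);
    for (int k = 0; k < n_xo; k++) xo_per_locus[rng.unif_int(lay.n_loci)]++;
    size_t i1 = 0, i2 = 0;
    for (int l = 0; l < lay.n_loci; l++) {
      size_t a1 = i1, a2 = i2;
      while (i1 < g1.size() && tab.locus[g1[i1]] == l) i1++;
      while (i2 < g2.size() && tab.locus[g2[i2]] == l) i2++;
      bool use_first = (coins >> l) & 1ULL;
      int k_l = xo_per_locus[l];
      if (k_l == 0) {
        const std::vector<int> &src = use_first ? g1 : g2;
        size_t from = use_first ? a1 : a2, to = use_first ? i1 : i2;
        for (size_t j = from; j < to; j++) {
          int id = src[j];
          out.push_back(id);
          tab.count[id]++;
          eff_sum += tab.effect[id];
        }
      } else {
        xo_pos.clear();
        for (int k = 0; k < k_l; k++)
          xo_pos.push_back(rng.unif() * lay.locus_len);
        std::sort(xo_pos.begin(), xo_pos.end());
        size_t c1 = a1, c2 = a2, bp = 0;
        bool cur_first = use_first;
        while (true) {
          double p1 = (c1 < i1) ? tab.pos[g1[c1]] : 1e300;
          double p2 = (c2 < i2) ? tab.pos[g2[c2]] : 1e300;
          double pmin = std::min(p1, p2);
          if (bp < xo_pos.size() && xo_pos[bp] <= pmin) {
            cur_first = !cur_first;
            bp++;
            continue;
          }
          if (pmin >= 1e299) break;
          if (p1 <= p2) {
            if (cur_first) {
              out.push_back(g1[c1]);
              tab.count[g1[c1]]++;
              eff_sum += tab.effect[g1[c1]];
            }
            c1++;
          } else {
            if (!cur_first) {
              out.push_back(g2[c2]);
              tab.count[g2[c2]]++;
              eff_sum += tab.effect[g2[c2]];
            }
            c2++;
          }
        }
      }
    }
  }

  // new mutations: count ~ Poisson(U); locus uniform; genic vs intergenic
  // class by length-weighted rate; position continuous (infinite sites)
  int n_mut = rng.poisson(lay.U, lay.p0_U);
  for (int m = 0; m < n_mut; m++) {
    int loc = rng.unif_int(lay.n_loci);
    double flank = (lay.locus_len - lay.genic_len) / 2.0;
    double p;
    if (rng.unif() < lay.genic_frac) {
      p = flank + rng.unif() * lay.genic_len;
    } else {
      double u = rng.unif() * (lay.locus_len - lay.genic_len);
      p = (u < flank) ? u : u + lay.genic_len;
    }
    double a = sigma_m * rng.normal();
    int slot = tab.alloc(loc, p, a, gen_label);
    tab.count[slot] = 1;
    auto it = out.begin();
    while (it != out.end() && mut_before(tab, *it, slot)) ++it;
    out.insert(it, slot);
    eff_sum += a;
  }
}

Pop pop_from_list(List st) {
  Pop pop;
  pop.gen = as<int>(st["generation"]);
  pop.baseline = as<double>(st["baseline"]);
  List gam = st["gametes"];
  pop.n = gam.size() / 2;
  pop.gam.resize(gam.size());
  DataFrame mut = as<DataFrame>(st["mutations"]);
  IntegerVector locus = mut["locus"];
  NumericVector pos = mut["pos"], effect = mut["effect"];
  IntegerVector origin = mut["origin"], count = mut["count"];
  int m = locus.size();
  pop.tab.locus.assign(locus.begin(), locus.end());
  for (int i = 0; i < m; i++) pop.tab.locus[i] -= 1;
  pop.tab.pos.assign(pos.begin(), pos.end());
  pop.tab.effect.assign(effect.begin(), effect.end());
  pop.tab.gkey.resize(m);
  pop.tab.origin.assign(origin.begin(), origin.end());
  pop.tab.count.assign(count.begin(), count.end());
  pop.tab.active.assign(m, 1);
  for (int i = 0; i < m; i++) pop.tab.active_list.push_back(i);
  for (int i = 0; i < (int)gam.size(); i++) {
    IntegerVector v = gam[i];
    pop.gam[i].assign(v.begin(), v.end());
    for (auto &id : pop.gam[i]) id -= 1;
  }
  NumericVector G = st["G"], P = st["P"];
  pop.G.assign(G.begin(), G.end());
  pop.P.assign(P.begin(), P.end());
  return pop;
}

List pop_to_list(Pop &pop) {
  int m = (int)pop.tab.locus.size();
  std::vector<int> remap(m, -1), keep;
  for (int i = 0; i < m; i++)
    if (pop.tab.active[i]) { remap[i] = (int)keep.size(); keep.push_back(i); }
  int k = (int)keep.size();
  IntegerVector locus(k), origin(k), count(k);
  NumericVector pos(k), effect(k);
  for (int i = 0; i < k; i++) {
    locus[i] = pop.tab.locus[keep[i]] + 1;
    pos[i] = pop.tab.pos[keep[i]];
    effect[i] = pop.tab.effect[keep[i]];
    origin[i] = pop.tab.origin[keep[i]];
    count[i] = pop.tab.count[keep[i]];
  }
  List gam(pop.gam.size());
  for (size_t i = 0; i < pop.gam.size(); i++) {
    IntegerVector v(pop.gam[i].size());
    for (size_t j = 0; j < pop.gam[i].size(); j++)
      v[j] = remap[pop.gam[i][j]] + 1;
    gam[i] = v;
  }
  DataFrame mut = DataFrame::create(
      _["locus"] = locus, _["pos"] = pos, _["effect"] = effect,
      _["origin"] = origin, _["count"] = count);
  return List::create(
      _["generation"] = pop.gen, _["gametes"] = gam, _["mutations"] = mut,
      _["baseline"] = pop.baseline, _["G"] = wrap(pop.G), _["P"] = wrap(pop.P));
}

DataFrame fate_to_df(const FateLog &log) {
  int n = (int)log.gen.size();
  IntegerVector locus(n), origin(n), gen(n);
  NumericVector pos(n), effect(n), p0(n);
  for (int i = 0; i < n; i++) {
    locus[i] = log.locus[i] + 1; pos[i] = log.pos[i];
    effect[i] = log.effect[i]; origin[i] = log.origin[i];
    gen[i] = log.gen[i]; p0[i] = log.p0[i];
  }
  return DataFrame::create(_["locus"] = locus, _["pos"] = pos,
                           _["effect"] = effect, _["origin"] = origin,
                           _["gen"] = gen, _["p0"] = p0);
}

List snapshot_of(const Pop &pop, bool with_genotypes) {
  int m = 0;
  for (char a : pop.tab.active) m += a;
  IntegerVector locus(m), origin(m), count(m), slot(m);
  NumericVector pos(m), effect(m);
  int j = 0;
  for (int i = 0; i < (int)pop.tab.active.size(); i++) {
    if (!pop.tab.active[i]) continue;
    slot[j] = i + 1;
    locus[j] = pop.tab.locus[i] + 1; pos[j] = pop.tab.pos[i];
    effect[j] = pop.tab.effect[i]; origin[j] = pop.tab.origin[i];
    count[j] = pop.tab.count[i];
    j++;
  }
  DataFrame mut = DataFrame::create(
      _["slot"] = slot, _["locus"] = locus, _["pos"] = pos,
      _["effect"] = effect, _["origin"] = origin, _["count"] = count);
  List out = List::create(
      _["generation"] = pop.gen, _["mutations"] = mut,
      _["n"] = pop.n, _["baseline"] = pop.baseline,
      _["G"] = wrap(pop.G), _["P"] = wrap(pop.P));
  if (with_genotypes) {
    List gam(pop.gam.size());
    for (size_t i = 0; i < pop.gam.size(); i++) {
      IntegerVector v(pop.gam[i].size());
      for (size_t jj = 0; jj < pop.gam[i].size(); jj++)
        v[jj] = pop.gam[i][jj] + 1;  // slot ids, 1-based
      gam[i] = v;
    }
    out["gametes"] = gam;
  }
  return out;
}

}  // namespace

// regime: 0 = stabilizing selection at z_opt throughout
//         1 = adaptation: truncation selection while the pre-selection mean
//             trait is below z_opt_new, then (permanently) stabilizing
//             selection at z_opt_new
//         2 = truncation selection at z_opt_new throughout
// [[Rcpp::export]]
List cpp_simulate(List state, IntegerVector schedule, int regime,
                  double z_opt, double z_opt_new,
                  double sigma_m, double V_S, double psi,
                  double U, int n_loci, double locus_len, double genic_len,
                  double genic_frac, double xo_mean,
                  bool background_qtl_midparent,
                  IntegerVector snapshot_gens,
                  bool track_fates, bool record_traj,
                  bool genotypes_in_snapshots) {
  Xoshiro rng;
  rng.seed_from_R();

  Pop pop = pop_from_list(state);
  Layout lay{n_loci, locus_len, genic_len, genic_frac, U, xo_mean,
             std::exp(-U), std::exp(-xo_mean)};
  pop.tab.key_span = locus_len + 1.0;
  for (size_t i = 0; i < pop.tab.gkey.size(); i++)
    pop.tab.gkey[i] = pop.tab.locus[i] * pop.tab.key_span + pop.tab.pos[i];

  int T = schedule.size();
  FateLog fixlog, losslog;
  std::vector<double> tr_mean, tr_vg, tr_varp, tr_meang;
  std::vector<int> tr_gen, tr_n, tr_phase;
  std::set<int> snap_set(snapshot_gens.begin(), snapshot_gens.end());
  std::vector<List> snaps;

  // frequency at entry (= the optimum shift, for adaptation runs), per slot
  std::vector<double> p0(pop.tab.locus.size(), 0.0);
  {
    double denom0 = 2.0 * pop.n;
    for (size_t i = 0; i < p0.size(); i++)
      if (pop.tab.active[i]) p0[i] = pop.tab.count[i] / denom0;
  }

  bool truncation_over = false;
  int reached_gen = NA_INTEGER;

  std::vector<double> cumw;
  std::vector<int> survivors, xo_per_locus;
  std::vector<double> xo_pos;
  std::vector<std::vector<int>> new_gam;
  std::vector<double> newG, newP;

  for (int step = 0; step < T; step++) {
    int n_next = schedule[step];
    int gen_next = pop.gen + 1;
    int n_cur = pop.n;

    double meanP = 0.0, varP = 0.0;
    for (double v : pop.P) meanP += v;
    meanP /= n_cur;
    for (double v : pop.P) varP += (v - meanP) * (v - meanP);
    varP /= n_cur;

    bool truncate;
    double zopt_cur;
    if (regime == 0) { truncate = false; zopt_cur = z_opt; }
    else if (regime == 2) { truncate = true; zopt_cur = z_opt_new; }
    else {
      bool shift_null = (z_opt_new == z_opt);
      if (!truncation_over && !shift_null && meanP >= z_opt_new) {
        truncation_over = true;
        reached_gen = pop.gen;
      }
      truncate = !shift_null && !truncation_over;
      zopt_cur = shift_null ? z_opt : z_opt_new;
    }

    int half = (n_cur + 1) / 2;  // ceil(n/2) survivors under truncation
    if (truncate) {
      // rank by squared distance to the optimum (monotone in Gaussian
      // fitness); ties broken by stable index order
      std::vector<std::pair<double, int>> d(n_cur);
      for (int i = 0; i < n_cur; i++) {
        double dev = pop.P[i] - zopt_cur;
        d[i] = {dev * dev, i};
      }
      std::stable_sort(d.begin(), d.end(),
                       [](const std::pair<double, int> &a,
                          const std::pair<double, int> &b) {
                         return a.first < b.first;
                       });
      survivors.resize(half);
      for (int i = 0; i < half; i++) survivors[i] = d[i].second;
    } else {
      cumw.resize(n_cur);
      double tot = 0.0;
      for (int i = 0; i < n_cur; i++) {
        double dev = pop.P[i] - zopt_cur;
        tot += std::exp(-dev * dev / (2.0 * V_S));
        cumw[i] = tot;
      }
      if (tot <= 0.0) stop("all fitness values are zero");
    }

    // reset counts of active mutations, dropping stale list entries
    {
      std::vector<int> fresh;
      fresh.reserve(pop.tab.active_list.size());
      for (int slot : pop.tab.active_list)
        if (pop.tab.active[slot]) {
          pop.tab.count[slot] = 0;
          fresh.push_back(slot);
        }
      pop.tab.active_list.swap(fresh);
    }

    new_gam.resize(2 * n_next);
    newG.assign(n_next, 0.0);
    newP.assign(n_next, 0.0);
    double totw = truncate ? 0.0 : cumw[n_cur - 1];
    double sdP = std::sqrt(varP);

    for (int j = 0; j < n_next; j++) {
      int pa, pb;
      if (truncate) {
        pa = survivors[rng.unif_int(half)];
        pb = survivors[rng.unif_int(half)];
      } else {
        double u1 = rng.unif() * totw, u2 = rng.unif() * totw;
        pa = (int)(std::lower_bound(cumw.begin(), cumw.end(), u1) - cumw.begin());
        pb = (int)(std::lower_bound(cumw.begin(), cumw.end(), u2) - cumw.begin());
        if (pa >= n_cur) pa = n_cur - 1;
        if (pb >= n_cur) pb = n_cur - 1;
      }
      double eff_sum = 0.0;
      meiosis(pop, pa, lay, sigma_m, rng, pop.tab, gen_next, new_gam[2 * j],
              eff_sum, xo_per_locus, xo_pos);
      meiosis(pop, pb, lay, sigma_m, rng, pop.tab, gen_next, new_gam[2 * j + 1],
              eff_sum, xo_per_locus, xo_pos);
      // effects are per-copy (heterozygous) values: genotype contributes
      // 0 / a / 2a for 0/1/2 copies, so G is the plain sum over copies
      double G = pop.baseline + eff_sum;
      double P;
      if (psi > 0.0) {
        double gmp = background_qtl_midparent
                         ? 0.5 * (pop.G[pa] + pop.G[pb])
                         : 0.5 * (pop.P[pa] + pop.P[pb]);
        double GB = gmp + sdP * rng.normal();
        P = psi * GB + (1.0 - psi) * G;
      } else {
        P = G;
      }
      newG[j] = G;
      newP[j] = P;
    }

    pop.gam.swap(new_gam);
    pop.G.swap(newG);
    pop.P.swap(newP);
    pop.n = n_next;
    pop.gen = gen_next;

    // fixations and losses
    int full = 2 * n_next;
    bool any_fixed = false;
    {
      std::vector<int> still;
      still.reserve(pop.tab.active_list.size());
      for (int slot : pop.tab.active_list) {
        if (!pop.tab.active[slot]) continue;
        int c = pop.tab.count[slot];
        if (c == 0) {
          if (track_fates)
            losslog.add(pop.tab, slot, gen_next,
                        (size_t)slot < p0.size() ? p0[slot] : 0.0);
          pop.tab.release(slot);
        } else if (c == full) {
          pop.baseline += 2.0 * pop.tab.effect[slot];  // homozygous everywhere
          if (track_fates)
            fixlog.add(pop.tab, slot, gen_next,
                       (size_t)slot < p0.size() ? p0[slot] : 0.0);
          pop.tab.release(slot);
          any_fixed = true;
        } else {
          still.push_back(slot);
        }
      }
      pop.tab.active_list.swap(still);
    }
    if (any_fixed) {
      for (auto &g : pop.gam) {
        size_t k = 0;
        for (size_t i = 0; i < g.size(); i++)
          if (pop.tab.active[g[i]]) g[k++] = g[i];
        g.resize(k);
      }
    }
    if (pop.tab.locus.size() > p0.size()) p0.resize(pop.tab.locus.size(), 0.0);

    if (record_traj) {
      double mG = 0.0, vG = 0.0, mP = 0.0, vP = 0.0;
      for (int i = 0; i < n_next; i++) { mG += pop.G[i]; mP += pop.P[i]; }
      mG /= n_next; mP /= n_next;
      for (int i = 0; i < n_next; i++) {
        vG += (pop.G[i] - mG) * (pop.G[i] - mG);
        vP += (pop.P[i] - mP) * (pop.P[i] - mP);
      }
      vG /= n_next; vP /= n_next;
      tr_gen.push_back(gen_next); tr_n.push_back(n_next);
      tr_mean.push_back(mP); tr_meang.push_back(mG);
      tr_vg.push_back(vG); tr_varp.push_back(vP);
      tr_phase.push_back(truncate ? 1 : 0);
    }
    if (snap_set.count(gen_next))
      snaps.push_back(snapshot_of(pop, genotypes_in_snapshots));

    if ((step & 255) == 0) Rcpp::checkUserInterrupt();
  }

  // regime 1: population may reach the optimum exactly at the final recorded
  // generation; check once more so reached_gen is not missed by one step
  if (regime == 1 && !truncation_over && z_opt_new != z_opt) {
    double meanP = 0.0;
    for (double v : pop.P) meanP += v;
    meanP /= pop.n;
    if (meanP >= z_opt_new) reached_gen = pop.gen;
  }

  RObject traj = R_NilValue;
  if (record_traj) {
    traj = DataFrame::create(
        _["generation"] = wrap(tr_gen), _["n"] = wrap(tr_n),
        _["mean_trait"] = wrap(tr_mean), _["mean_G"] = wrap(tr_meang),
        _["var_G"] = wrap(tr_vg), _["var_trait"] = wrap(tr_varp),
        _["truncation"] = wrap(tr_phase));
  }
  List snl(snaps.size());
  for (size_t i = 0; i < snaps.size(); i++) snl[i] = snaps[i];

  return List::create(
      _["state"] = pop_to_list(pop), _["trajectory"] = traj,
      _["snapshots"] = snl,
      _["fixations"] = fate_to_df(fixlog),
      _["losses"] = fate_to_df(losslog),
      _["reached_gen"] = reached_gen == NA_INTEGER
                             ? IntegerVector::create(NA_INTEGER)
                             : IntegerVector::create(reached_gen));
}
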