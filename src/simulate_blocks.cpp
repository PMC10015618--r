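#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent simulator for one diploid sampled from each of two
// species (2 + 2 haplotypes) under a two-epoch history: two demes (A, B) with
// unidirectional backwards migration until the split time, a single ancestral
// deme beyond it. Works with labelled lineages so that per-haplotype pairwise
// coalescence times are available in addition to the four unphased,
// unpolarised block mutation types.
//
// Haplotype bits: 1 = a1, 2 = a2, 4 = b1, 8 = b2.

namespace {

inline int popcount4(int x) {
  return ((x & 1) != 0) + ((x & 2) != 0) + ((x & 4) != 0) + ((x & 8) != 0);
}

// Mutation type of a branch subtending `mask`:
// 0 hetA, 1 hetB, 2 hetAB, 3 fixed, -1 unobservable (root).
inline int branch_type(int mask) {
  const int na = popcount4(mask & 3);
  const int nb = popcount4(mask & 12);
  if (na == 1 && nb == 0) return 0;
  if (na == 0 && nb == 1) return 1;
  if (na == 1 && nb == 1) return 2;
  if ((na == 2 && nb == 0) || (na == 0 && nb == 2)) return 3;
  if (na == 2 && nb == 1) return 1;  // complement is a singleton of B
  if (na == 1 && nb == 2) return 0;  // complement is a singleton of A
  return -1;                         // na == 2 && nb == 2: above the MRCA
}

struct Genealogy {
  double L[4];      // branch length per mutation type, generations
  double cross_ab;  // time a1 and b1 sit on distinct lineages
  double within_a;  // likewise a1 vs a2
  double within_b;  // likewise b1 vs b2
  double total;     // total observable branch length
};

// One realisation of the block genealogy. mig_src is the deme whose lineages
// jump (backwards in time) into the other deme: 0 = deme A, 1 = deme B,
// -1 = no migration.
Genealogy simulate_genealogy(double ne_a, double ne_b, double ne_anc,
                             double split_time, double me, int mig_src) {
  int mask[4] = {1, 2, 4, 8};
  int deme[4] = {0, 0, 1, 1};
  int n = 4;
  Genealogy g = {{0.0, 0.0, 0.0, 0.0}, 0.0, 0.0, 0.0, 0.0};

  double t = 0.0;
  bool ancestral = split_time <= 0.0;
  if (ancestral) t = split_time;

  auto accumulate = [&](double dt) {
    for (int i = 0; i < n; ++i) {
      const int ty = branch_type(mask[i]);
      if (ty >= 0) g.L[ty] += dt;
    }
    g.total += n * dt;
    // pair separation times
    bool a1b1 = false, a1a2 = false, b1b2 = false;
    for (int i = 0; i < n; ++i) {
      const int m = mask[i];
      if ((m & 1) && (m & 4)) a1b1 = true;
      if ((m & 1) && (m & 2)) a1a2 = true;
      if ((m & 4) && (m & 8)) b1b2 = true;
    }
    if (!a1b1) g.cross_ab += dt;
    if (!a1a2) g.within_a += dt;
    if (!b1b2) g.within_b += dt;
  };

  while (n > 1) {
    double rate_coal[2] = {0.0, 0.0};
    double rate_mig = 0.0;
    int cnt[2] = {0, 0};
    if (!ancestral) {
      for (int i = 0; i < n; ++i) ++cnt[deme[i]];
      rate_coal[0] = cnt[0] * (cnt[0] - 1) / 2.0 / (2.0 * ne_a);
      rate_coal[1] = cnt[1] * (cnt[1] - 1) / 2.0 / (2.0 * ne_b);
      if (mig_src >= 0) rate_mig = cnt[mig_src] * me;
    } else {
      cnt[0] = n;
      rate_coal[0] = n * (n - 1) / 2.0 / (2.0 * ne_anc);
    }
    const double total_rate = rate_coal[0] + rate_coal[1] + rate_mig;

    double dt;
    if (total_rate <= 0.0) {
      dt = R_PosInf;
    } else {
      dt = R::rexp(1.0 / total_rate);
    }

    if (!ancestral && t + dt >= split_time) {
      accumulate(split_time - t);
      t = split_time;
      ancestral = true;
      continue;
    }
    accumulate(dt);
    t += dt;

    const double u = R::runif(0.0, total_rate);
    if (u < rate_coal[0] + rate_coal[1]) {
      const int d = (u < rate_coal[0]) ? 0 : (ancestral ? 0 : 1);
      // choose an unordered pair within deme d
      const int nd = ancestral ? n : cnt[d];
      const int npair = nd * (nd - 1) / 2;
      int pick = (int)std::floor(R::runif(0.0, npair));
      if (pick >= npair) pick = npair - 1;
      int first = -1, second = -1, seen = 0, k = 0;
      for (int i = 0; i < n && first < 0; ++i) {
        if (!ancestral && deme[i] != d) continue;
        int seen_j = 0;
        for (int j = i + 1; j < n; ++j) {
          if (!ancestral && deme[j] != d) continue;
          if (k == pick) { first = i; second = j; break; }
          ++k;
          ++seen_j;
        }
        (void)seen;
        (void)seen_j;
      }
      mask[first] |= mask[second];
      mask[second] = mask[n - 1];
      deme[second] = deme[n - 1];
      --n;
    } else {
      // migration: a uniformly chosen lineage in the source deme jumps
      int pick = (int)std::floor(R::runif(0.0, cnt[mig_src]));
      if (pick >= cnt[mig_src]) pick = cnt[mig_src] - 1;
      int k = 0;
      for (int i = 0; i < n; ++i) {
        if (deme[i] == mig_src) {
          if (k == pick) { deme[i] = 1 - mig_src; break; }
          ++k;
        }
      }
    }
  }
  return g;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_blocks")]]
IntegerMatrix cpp_simulate_blocks(int n_blocks, double ne_a, double ne_b,
                                  double ne_anc, double split_time, double me,
                                  int mig_src, double mu, int block_span,
                                  bool linked, double recomb_rate) {
  IntegerMatrix out(n_blocks, 7);
  colnames(out) = CharacterVector::create("hetA", "hetB", "hetAB", "fixed",
                                          "cross_ab", "within_a", "within_b");
  const double mu_block = mu * block_span;
  Genealogy g;
  bool have_g = false;

  // Linked mode: renewal approximation to the sequential coalescent. The
  // genealogy persists across neighbouring blocks and is replaced by an
  // independent draw with a probability matched to the chance of at least
  // one recombination on a typical tree between block midpoints. The
  // refresh probability uses the expected total branch length (pilot
  // estimate) rather than the realized one, so refreshes are independent of
  // the current tree and the marginal block distribution stays exactly the
  // coalescent; only the correlation structure is approximate.
  double p_keep = 0.0;
  if (linked && n_blocks > 1) {
    double mean_len = 0.0;
    const int npilot = 256;
    for (int i = 0; i < npilot; ++i) {
      mean_len += simulate_genealogy(ne_a, ne_b, ne_anc, split_time, me,
                                     mig_src).total;
    }
    mean_len /= npilot;
    p_keep = std::exp(-recomb_rate * block_span * mean_len);
  }

  for (int i = 0; i < n_blocks; ++i) {
    if (i % 8192 == 0) Rcpp::checkUserInterrupt();
    bool fresh = !have_g || !linked;
    if (!fresh) fresh = R::runif(0.0, 1.0) > p_keep;
    if (fresh) {
      g = simulate_genealogy(ne_a, ne_b, ne_anc, split_time, me, mig_src);
      have_g = true;
    }
    out(i, 0) = (int)R::rpois(mu_block * g.L[0]);
    out(i, 1) = (int)R::rpois(mu_block * g.L[1]);
    out(i, 2) = (int)R::rpois(mu_block * g.L[2]);
    out(i, 3) = (int)R::rpois(mu_block * g.L[3]);
    out(i, 4) = (int)R::rpois(mu_block * 2.0 * g.cross_ab);
    out(i, 5) = (int)R::rpois(mu_block * 2.0 * g.within_a);
    out(i, 6) = (int)R::rpois(mu_block * 2.0 * g.within_b);
  }
  return out;
}
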