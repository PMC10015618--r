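#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact probabilities of joint block mutation-type counts (hetA, hetB, hetAB,
// fixed), truncated at kmax with an absorbing overflow level per type, for a
// 2 + 2 haplotype block under a two-epoch structured coalescent.
//
// The chain lives on (genealogical configuration) x (count vector). The
// configuration graph is enumerated in R once and passed in as edge lists with
// per-call rates (already in coalescent units of 2*Ne_ref generations):
//
//   epoch 1: two demes, coalescence + unidirectional migration, solved with
//            uniformization up to the scaled split time;
//   epoch 2: one deme; both the configuration transitions (coalescence only)
//            and the count increments are monotone, so absorption
//            probabilities follow from a single forward pass over the DAG.
//
// Counts run 0..kmax+1 per type; level kmax+1 ("overflow") saturates, i.e.
// further mutations of that type are no longer events.

// [[Rcpp::export(name = ".cpp_bsfs_kernel")]]
NumericVector cpp_bsfs_kernel(IntegerVector e1_from, IntegerVector e1_to,
                              NumericVector e1_rate, IntegerMatrix mut1,
                              int init1, IntegerVector map12,
                              IntegerVector e2_from, IntegerVector e2_to,
                              NumericVector e2_rate, IntegerMatrix mut2,
                              int abs2, double theta_half, double t_scaled,
                              IntegerVector kmax) {
  const int n1 = mut1.nrow();
  const int n2 = mut2.nrow();
  const int ntype = 4;
  int D[4], stride[4];
  int B = 1;
  for (int t = 0; t < ntype; ++t) {
    D[t] = kmax[t] + 2;
    stride[t] = B;
    B *= D[t];
  }
  // digits of every bin, and per-bin/per-type "can still mutate" flag
  std::vector<int> digit(B * ntype);
  for (int b = 0; b < B; ++b) {
    int r = b;
    for (int t = 0; t < ntype; ++t) {
      digit[b * ntype + t] = r % D[t];
      r /= D[t];
    }
  }

  const int ne1 = e1_from.size();
  std::vector<double> cfg_exit1(n1, 0.0);
  for (int e = 0; e < ne1; ++e) cfg_exit1[e1_from[e]] += e1_rate[e];
  std::vector<double> mrate1(n1 * ntype);
  double max_mut1 = 0.0;
  for (int c = 0; c < n1; ++c) {
    double s = 0.0;
    for (int t = 0; t < ntype; ++t) {
      mrate1[c * ntype + t] = theta_half * mut1(c, t);
      s += mrate1[c * ntype + t];
    }
    if (s > max_mut1) max_mut1 = s;
  }
  // uniformization rate over configurations actually reachable from the
  // initial state given the (direction-dependent) nonzero rates; the shared
  // template enumerates both migration directions, so the global maximum
  // would overestimate the rate and waste steps
  std::vector<char> reach(n1, 0);
  reach[init1] = 1;
  for (bool grew = true; grew;) {
    grew = false;
    for (int e = 0; e < ne1; ++e) {
      if (e1_rate[e] > 0.0 && reach[e1_from[e]] && !reach[e1_to[e]]) {
        reach[e1_to[e]] = 1;
        grew = true;
      }
    }
  }
  double lambda_reach = 0.0;
  for (int c = 0; c < n1; ++c) {
    if (!reach[c]) continue;
    double s = cfg_exit1[c];
    for (int t = 0; t < ntype; ++t) s += mrate1[c * ntype + t];
    if (s > lambda_reach) lambda_reach = s;
  }
  (void)max_mut1;

  std::vector<double> v(n1 * B, 0.0);
  v[init1] = 1.0;  // bin 0, config init1 (state index c + n1*b)
  std::vector<char> act(B, 0);
  act[0] = 1;

  if (t_scaled > 0.0) {
    const double lambda = lambda_reach + 1e-12;
    const int nsub = std::max(1, (int)std::ceil(lambda * t_scaled / 400.0));
    const double dt = t_scaled / nsub;
    const double lt = lambda * dt;
    std::vector<double> w(n1 * B), acc(n1 * B);

    for (int sub = 0; sub < nsub; ++sub) {
      Rcpp::checkUserInterrupt();
      // res = sum_n Pois(n; lt) P^n v
      double logw = -lt;  // log Poisson weight at n = 0
      double cum = 0.0;
      std::fill(acc.begin(), acc.end(), 0.0);
      double wn = std::exp(logw);
      for (size_t s = 0; s < v.size(); ++s) acc[s] = wn * v[s];
      cum = wn;
      int n = 0;
      const int nmax = (int)std::ceil(lt + 12.0 * std::sqrt(lt + 1.0) + 40.0);
      while (cum < 1.0 - 1e-13 && n < nmax) {
        ++n;
        // w = P v,  P = I + Q/lambda (only bins that already carry mass
        // can contribute; mutation jumps activate new bins as they fill)
        std::fill(w.begin(), w.end(), 0.0);
        for (int b = 0; b < B; ++b) {
          if (!act[b]) continue;
          const int off = n1 * b;
          // configuration transitions (counts unchanged)
          for (int e = 0; e < ne1; ++e) {
            const double x = v[e1_from[e] + off];
            if (x != 0.0) w[e1_to[e] + off] += x * (e1_rate[e] / lambda);
          }
          // mutation increments and the diagonal
          const int* dg = &digit[b * ntype];
          for (int c = 0; c < n1; ++c) {
            const double x = v[c + off];
            if (x == 0.0) continue;
            double exit = cfg_exit1[c];
            for (int t = 0; t < ntype; ++t) {
              if (dg[t] < D[t] - 1) {
                const double mr = mrate1[c * ntype + t];
                if (mr != 0.0) {
                  exit += mr;
                  w[c + off + n1 * stride[t]] += x * (mr / lambda);
                  act[b + stride[t]] = 1;
                }
              }
            }
            w[c + off] += x * (1.0 - exit / lambda);
          }
        }
        v.swap(w);
        logw += std::log(lt) - std::log((double)n);
        wn = std::exp(logw);
        cum += wn;
        if (wn > 0.0)
          for (size_t s = 0; s < v.size(); ++s) acc[s] += wn * v[s];
      }
      // renormalise the tiny truncated tail so mass is conserved
      if (cum > 0.0 && cum < 1.0)
        for (size_t s = 0; s < acc.size(); ++s) acc[s] /= cum;
      v.swap(acc);
    }
  }

  // hand over to the single ancestral deme
  std::vector<double> w2(n2 * B, 0.0);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < n1; ++c) {
      const double x = v[c + n1 * b];
      if (x != 0.0) w2[map12[c] + n2 * b] += x;
    }

  const int ne2 = e2_from.size();
  std::vector<double> cfg_exit2(n2, 0.0);
  for (int e = 0; e < ne2; ++e) cfg_exit2[e2_from[e]] += e2_rate[e];

  NumericVector out(B);
  // epoch-2 configurations arrive topologically sorted (decreasing lineage
  // count); counts only increase, so one forward sweep suffices
  for (int b = 0; b < B; ++b) {
    const int off = n2 * b;
    const int* dg = &digit[b * ntype];
    for (int c = 0; c < n2; ++c) {
      const double x = w2[c + off];
      if (x == 0.0) continue;
      if (c == abs2) {
        out[b] += x;
        continue;
      }
      double tot = cfg_exit2[c];
      double mr[4];
      for (int t = 0; t < ntype; ++t) {
        mr[t] = (dg[t] < D[t] - 1) ? theta_half * mut2(c, t) : 0.0;
        tot += mr[t];
      }
      for (int e = 0; e < ne2; ++e)
        if (e2_from[e] == c) w2[e2_to[e] + off] += x * (e2_rate[e] / tot);
      for (int t = 0; t < ntype; ++t)
        if (mr[t] != 0.0) w2[c + off + n2 * stride[t]] += x * (mr[t] / tot);
      w2[c + off] = 0.0;
    }
  }
  return out;
}
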