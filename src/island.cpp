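// Coalescent simulation of unlinked loci in a finite symmetric island model,
// used to build the neutral (He, FST) null cloud for the outlier scan.
//
// Time is measured in units of 2N (deme size). Within a deme each lineage
// pair coalesces at rate 1; each lineage migrates at rate M/2 with
// M = 4Nm, landing on a uniformly chosen other deme. Mutations are placed
// on branches at rate theta_eq / (2 * n_demes) per lineage, theta_eq being
// the metapopulation-scale 4*N*d*mu, so theta_eq controls total
// heterozygosity. mig_M < 0 requests panmixia (single pool, mutation rate
// theta_eq / 2).

#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Nei-Chesser corrected (Hs, Ht) and GST from sampled allele states.
// copies are ordered population by population (2*nd[j] copies each).
static void nei_chesser_stats(const std::vector<int> &state,
                              const IntegerVector &nd,
                              double &he, double &fst) {
  const int k = nd.size();
  std::map<int, int> aidx;
  for (size_t i = 0; i < state.size(); ++i)
    aidx.emplace(state[i], 0);
  int na = 0;
  for (auto &kv : aidx) kv.second = na++;
  if (na < 2) { he = 0.0; fst = NA_REAL; return; }

  std::vector<double> freq((size_t)k * na, 0.0);
  int pos = 0;
  for (int j = 0; j < k; ++j) {
    const int nc = 2 * nd[j];
    for (int c = 0; c < nc; ++c, ++pos)
      freq[(size_t)j * na + aidx[state[pos]]] += 1.0 / nc;
  }
  double hs_raw = 0.0, nh_inv = 0.0;
  for (int j = 0; j < k; ++j) {
    double sp2 = 0.0;
    for (int a = 0; a < na; ++a) {
      const double p = freq[(size_t)j * na + a];
      sp2 += p * p;
    }
    hs_raw += (1.0 - sp2) / k;
    nh_inv += 1.0 / nd[j];
  }
  const double nh = k / nh_inv;
  const double hs = (2.0 * nh / (2.0 * nh - 1.0)) * hs_raw;
  double sbar2 = 0.0;
  for (int a = 0; a < na; ++a) {
    double pbar = 0.0;
    for (int j = 0; j < k; ++j) pbar += freq[(size_t)j * na + a] / k;
    sbar2 += pbar * pbar;
  }
  const double ht = (1.0 - sbar2) + hs / (2.0 * nh * k);
  he = hs;
  fst = (ht > 0.0) ? (ht - hs) / ht : NA_REAL;
}

// [[Rcpp::export]]
NumericMatrix cpp_island_cloud(IntegerVector sample_sizes, int n_demes,
                               double mig_M, NumericVector theta,
                               int model, double gsm_p) {
  const int k = sample_sizes.size();
  const int n_loci = theta.size();
  int L0 = 0;
  for (int j = 0; j < k; ++j) L0 += 2 * sample_sizes[j];
  const bool panmictic = mig_M < 0.0;
  if (!panmictic && n_demes < k)
    stop("n_demes must be at least the number of sampled populations");

  NumericMatrix out(n_loci, 2);
  const int n_nodes = 2 * L0 - 1;
  std::vector<int> parent(n_nodes), active(L0), deme(L0);
  std::vector<double> ntime(n_nodes), blen(n_nodes);
  std::vector<int> cnt(std::max(n_demes, 1));
  std::vector<int> members(L0);
  std::vector<int> state(n_nodes);

  for (int l = 0; l < n_loci; ++l) {
    if (l % 256 == 0) Rcpp::checkUserInterrupt();
    // init: samples of deme j occupy demes 0..k-1
    std::fill(cnt.begin(), cnt.end(), 0);
    int pos = 0;
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < 2 * sample_sizes[j]; ++c, ++pos) {
        active[pos] = pos;
        deme[pos] = panmictic ? 0 : j;
        ntime[pos] = 0.0;
      }
    if (panmictic) cnt[0] = L0;
    else for (int j = 0; j < k; ++j) cnt[j] = 2 * sample_sizes[j];

    double W = 0.0; // sum over demes of n(n-1)
    for (int d = 0; d < n_demes; ++d) W += (double)cnt[d] * (cnt[d] - 1);

    int A = L0, nxt = L0;
    double t = 0.0;
    while (A > 1) {
      const double rate_c = panmictic ? (double)A * (A - 1) / 2.0 : W / 2.0;
      const double rate_m = panmictic ? 0.0 : A * mig_M / 2.0;
      const double tot = rate_c + rate_m;
      t += R::rexp(1.0 / tot);
      if (unif_rand() * tot < rate_c) {
        // coalescence: choose deme with prob proportional to n(n-1)
        int d0 = 0;
        if (!panmictic) {
          double u = unif_rand() * W, acc = 0.0;
          for (int d = 0; d < n_demes; ++d) {
            acc += (double)cnt[d] * (cnt[d] - 1);
            if (u <= acc) { d0 = d; break; }
          }
        }
        // collect active slots in that deme (deme[] is per active slot)
        int nm = 0;
        for (int a = 0; a < A; ++a)
          if (panmictic || deme[a] == d0) members[nm++] = a;
        int i1 = (int)(unif_rand() * nm);
        int i2 = (int)(unif_rand() * (nm - 1));
        if (i2 >= i1) ++i2;
        int s1 = members[i1], s2 = members[i2];
        const int nn = nxt++;
        ntime[nn] = t;
        parent[active[s1]] = nn;
        parent[active[s2]] = nn;
        blen[active[s1]] = t - ntime[active[s1]];
        blen[active[s2]] = t - ntime[active[s2]];
        active[s1] = nn; // stays in d0
        active[s2] = active[A - 1];
        deme[s2] = deme[A - 1];
        --A;
        if (!panmictic) {
          W -= 2.0 * (cnt[d0] - 1);
          cnt[d0]--;
        }
      } else {
        // migration
        const int s = (int)(unif_rand() * A);
        const int d0 = deme[s];
        int d1 = (int)(unif_rand() * (n_demes - 1));
        if (d1 >= d0) ++d1;
        W += -2.0 * (cnt[d0] - 1) + 2.0 * cnt[d1];
        cnt[d0]--; cnt[d1]++;
        deme[s] = d1;
      }
    }
    const int root = nxt - 1;
    blen[root] = 0.0;

    // drop mutations from the root down (parent ids always exceed child ids)
    const double mrate = panmictic ? theta[l] / 2.0
                                   : theta[l] / (2.0 * n_demes);
    int iam_counter = 0;
    state[root] = 0;
    for (int v = root - 1; v >= 0; --v) {
      int s = state[parent[v]];
      const int nm = (int)R::rpois(blen[v] * mrate);
      if (nm > 0) {
        if (model == 1) { // infinite alleles
          s = ++iam_counter;
        } else if (model == 0) { // strict stepwise
          const int up = (int)R::rbinom(nm, 0.5);
          s += 2 * up - nm;
        } else { // generalized stepwise: geometric step sizes
          for (int m = 0; m < nm; ++m) {
            const int step = 1 + (int)R::rgeom(1.0 - gsm_p);
            s += (unif_rand() < 0.5) ? -step : step;
          }
        }
      }
      state[v] = s;
    }

    std::vector<int> leaf(state.begin(), state.begin() + L0);
    double he, fst;
    nei_chesser_stats(leaf, sample_sizes, he, fst);
    out(l, 0) = he;
    out(l, 1) = fst;
  }
  return out;
}
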