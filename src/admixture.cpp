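// Gibbs sampler for the admixture model of model-based Bayesian clustering:
// each allele copy carries a latent cluster assignment; cluster allele
// frequencies get Dirichlet(lambda + counts) updates, individual admixture
// proportions get Dirichlet(alpha + counts) updates (alpha fixed, no
// correlated-frequencies model). Returns posterior-mean admixture and the
// ln P(X|K) estimate mean(lnL) - var(lnL)/2 used for cluster-number
// selection.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// geno: n x 2L matrix of 0-based allele indices (-1 = missing), columns
// 2l, 2l+1 holding the two copies at locus l.
// [[Rcpp::export]]
List cpp_admixture_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                         int burn_in, int n_iter, double alpha,
                         double lambda, int thin_trace) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");
  if (K > n) stop("K exceeds the number of individuals");

  std::vector<int> ofs(L + 1, 0);
  for (int l = 0; l < L; ++l) ofs[l + 1] = ofs[l] + n_alleles[l];
  const int totA = ofs[L];

  // cluster allele frequencies P[k][ofs[l]+a], admixture Q[i][k]
  std::vector<double> P((size_t)K * totA), Q((size_t)n * K, 1.0 / K);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      for (int a = 0; a < n_alleles[l]; ++a)
        P[(size_t)k * totA + ofs[l] + a] = 1.0 / n_alleles[l];

  std::vector<double> cntP((size_t)K * totA), cntQ((size_t)n * K);
  std::vector<double> w(K), Qacc((size_t)n * K, 0.0);
  double s_ll = 0.0, s_ll2 = 0.0;
  const int kept = n_iter - burn_in;
  std::vector<double> trace;
  trace.reserve(n_iter / std::max(thin_trace, 1) + 1);

  for (int it = 0; it < n_iter; ++it) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *qi = &Q[(size_t)i * K];
      for (int c = 0; c < 2 * L; ++c) {
        const int a = geno(i, c);
        if (a < 0) continue;
        const int l = c >> 1;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          w[k] = qi[k] * P[(size_t)k * totA + ofs[l] + a];
          tot += w[k];
        }
        ll += std::log(tot);
        double u = unif_rand() * tot, acc = 0.0;
        int z = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += w[k];
          if (u <= acc) { z = k; break; }
        }
        cntP[(size_t)z * totA + ofs[l] + a] += 1.0;
        cntQ[(size_t)i * K + z] += 1.0;
      }
    }
    // Dirichlet updates
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        const size_t base = (size_t)k * totA + ofs[l];
        for (int a = 0; a < n_alleles[l]; ++a) {
          P[base + a] = R::rgamma(lambda + cntP[base + a], 1.0);
          s += P[base + a];
        }
        for (int a = 0; a < n_alleles[l]; ++a) P[base + a] /= s;
      }
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const size_t base = (size_t)i * K;
      for (int k = 0; k < K; ++k) {
        Q[base + k] = R::rgamma(alpha + cntQ[base + k], 1.0);
        s += Q[base + k];
      }
      for (int k = 0; k < K; ++k) Q[base + k] /= s;
    }
    if (thin_trace > 0 && it % thin_trace == 0) trace.push_back(ll);
    if (it >= burn_in) {
      s_ll += ll; s_ll2 += ll * ll;
      for (size_t j = 0; j < Qacc.size(); ++j) Qacc[j] += Q[j];
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qacc[(size_t)i * K + k] / kept;
  const double mean_ll = s_ll / kept;
  const double var_ll = (kept > 1)
    ? (s_ll2 - kept * mean_ll * mean_ll) / (kept - 1) : 0.0;
  return List::create(_["Q"] = Qmean,
                      _["mean_ll"] = mean_ll,
                      _["var_ll"] = var_ll,
                      _["lnPK"] = mean_ll - var_ll / 2.0,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
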