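// Coalescent simulation of two sampled populations under three
// divergence-with-bottleneck scenarios, with a generalized stepwise
// mutation model (geometric step sizes, 40 reflecting motif states) plus a
// single-nucleotide-indel side channel, and the DIYABC-style summary
// statistics computed from the resulting samples.
//
// Scenarios (backward in time, generations):
//   1: pop1 ancestral (constant N1); pop2 at N2 until t1-db, Nb during the
//      bottleneck interval [t1-db, t1), then merges into pop1.
//   2: mirror image (pop2 ancestral, pop1 bottlenecked).
//   3: both pops bottlenecked on [t1-db, t1), merging at t1 into an
//      unsampled ancestor of size Nanc.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int MOTIF_STATES = 40; // reflecting bounds 0..39
static const int MOTIF_LEN = 3;     // nt per repeat unit
static const int SIZE_OFFSET = 100; // keeps reported allele sizes positive

struct SimParams {
  int scenario;
  double N1, N2, Nanc, Nb, t1, db, mu, gsm_p, sni;
};

// sizes of the two demes during phase 0 ([0, t1-db)) and 1 ([t1-db, t1))
static void phase_sizes(const SimParams &p, int phase, double &s1,
                        double &s2) {
  s1 = p.N1; s2 = p.N2;
  if (phase == 1) {
    if (p.scenario == 1) s2 = p.Nb;
    else if (p.scenario == 2) s1 = p.Nb;
    else { s1 = p.Nb; s2 = p.Nb; }
  }
}

static int reflect_motif(int m) {
  while (m < 0 || m >= MOTIF_STATES) {
    if (m < 0) m = -m;
    if (m >= MOTIF_STATES) m = 2 * (MOTIF_STATES - 1) - m;
  }
  return m;
}

// simulate one locus; writes allele sizes for the 2*(n1+n2) sampled copies
// (pop1 copies first) into out.
static void sim_locus(const SimParams &p, int n1, int n2, int *out,
                      std::vector<int> &parent, std::vector<double> &ntime,
                      std::vector<double> &blen) {
  const int L0 = 2 * (n1 + n2);
  const int n_nodes = 2 * L0 - 1;
  // active lineages per deme as node-id lists
  std::vector<int> d1, d2;
  d1.reserve(L0); d2.reserve(L0);
  for (int i = 0; i < 2 * n1; ++i) d1.push_back(i);
  for (int i = 2 * n1; i < L0; ++i) d2.push_back(i);
  std::fill(ntime.begin(), ntime.begin() + L0, 0.0);

  double t = 0.0;
  int phase = 0; // 0: pre-bottleneck, 1: bottleneck, 2: merged
  int nxt = L0;
  const double e0 = p.t1 - p.db, e1 = p.t1;
  double anc_size = (p.scenario == 1) ? p.N1
                    : (p.scenario == 2) ? p.N2 : p.Nanc;

  auto coal_pair = [&](std::vector<int> &dm) {
    const int n = dm.size();
    int i1 = (int)(unif_rand() * n);
    int i2 = (int)(unif_rand() * (n - 1));
    if (i2 >= i1) ++i2;
    const int c1 = dm[i1], c2 = dm[i2];
    const int nn = nxt++;
    ntime[nn] = t;
    parent[c1] = nn; parent[c2] = nn;
    blen[c1] = t - ntime[c1];
    blen[c2] = t - ntime[c2];
    // replace c1 by the new node, drop c2
    dm[i1] = nn;
    dm[i2] = dm.back();
    if (i2 == i1) dm[i1] = nn; // unreachable; kept for clarity
    dm.pop_back();
  };

  while ((int)d1.size() + (int)d2.size() > 1) {
    if (phase < 2) {
      double s1, s2;
      phase_sizes(p, phase, s1, s2);
      const double n1a = d1.size(), n2a = d2.size();
      const double r1 = n1a * (n1a - 1) / (4.0 * s1);
      const double r2 = n2a * (n2a - 1) / (4.0 * s2);
      const double tot = r1 + r2;
      const double bound = (phase == 0) ? e0 : e1;
      double dt = (tot > 0) ? R::rexp(1.0 / tot) : R_PosInf;
      if (t + dt >= bound) {
        t = bound;
        ++phase;
        if (phase == 2) { // merge: all lineages into the ancestral pool
          d1.insert(d1.end(), d2.begin(), d2.end());
          d2.clear();
        }
        continue;
      }
      t += dt;
      if (unif_rand() * tot < r1) coal_pair(d1); else coal_pair(d2);
    } else {
      const double na = d1.size();
      const double r = na * (na - 1) / (4.0 * anc_size);
      t += R::rexp(1.0 / r);
      coal_pair(d1);
    }
  }
  const int root = nxt - 1;
  blen[root] = 0.0;

  // mutations, root -> leaves; state = (motif index, indel offset)
  std::vector<int> motif(n_nodes), indel(n_nodes);
  motif[root] = MOTIF_STATES / 2;
  indel[root] = 0;
  for (int v = root - 1; v >= 0; --v) {
    int m = motif[parent[v]], id = indel[parent[v]];
    const int nmut = (int)R::rpois(blen[v] * p.mu);
    for (int x = 0; x < nmut; ++x) {
      const int step = 1 + (int)R::rgeom(1.0 - p.gsm_p);
      m = reflect_motif(m + ((unif_rand() < 0.5) ? -step : step));
    }
    const int nind = (int)R::rpois(blen[v] * p.sni);
    for (int x = 0; x < nind; ++x) id += (unif_rand() < 0.5) ? -1 : 1;
    motif[v] = m; indel[v] = id;
  }
  for (int i = 0; i < L0; ++i) {
    int sz = MOTIF_LEN * motif[i] + indel[i] + SIZE_OFFSET;
    if (sz < 1) sz = 1;
    out[i] = sz;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_sim_divergence(int n1, int n2, int n_loci, int scenario,
                                 double N1, double N2, double Nanc, double Nb,
                                 double t1, double db, double mu,
                                 double gsm_p, double sni) {
  if (scenario < 1 || scenario > 3) stop("scenario must be 1, 2 or 3");
  if (t1 <= db) stop("invalid draw: t1 must exceed db (in generations)");
  SimParams p{scenario, N1, N2, Nanc, Nb, t1, db, mu, gsm_p, sni};
  const int L0 = 2 * (n1 + n2);
  IntegerMatrix out(L0, n_loci);
  std::vector<int> parent(2 * L0 - 1);
  std::vector<double> ntime(2 * L0 - 1), blen(2 * L0 - 1);
  std::vector<int> buf(L0);
  for (int l = 0; l < n_loci; ++l) {
    sim_locus(p, n1, n2, buf.data(), parent, ntime, blen);
    for (int i = 0; i < L0; ++i) out(i, l) = buf[i];
  }
  return out;
}

// ---- summary statistics ---------------------------------------------------

// per-locus helper values for one population's copies
struct PopLocus {
  double A, sump2, var, range;
};

static PopLocus pop_locus(const int *copies, int nc) {
  PopLocus r;
  std::vector<int> v(copies, copies + nc);
  std::sort(v.begin(), v.end());
  int na = 1;
  for (int i = 1; i < nc; ++i) if (v[i] != v[i - 1]) ++na;
  r.A = na;
  double sp2 = 0.0;
  for (int i = 0; i < nc; ) {
    int j = i;
    while (j < nc && v[j] == v[i]) ++j;
    const double pfreq = (double)(j - i) / nc;
    sp2 += pfreq * pfreq;
    i = j;
  }
  r.sump2 = sp2;
  double mean = 0.0;
  for (int i = 0; i < nc; ++i) mean += v[i];
  mean /= nc;
  double ss = 0.0;
  for (int i = 0; i < nc; ++i) ss += (v[i] - mean) * (v[i] - mean);
  r.var = (nc > 1) ? ss / (nc - 1) : 0.0;
  r.range = v[nc - 1] - v[0];
  return r;
}

// Summary-statistic vector for a two-population sample of allele sizes.
// alleles: 2*(n1+n2) x n_loci, pop1 copies first. Order:
// A1, He1, V1, M1, A2, He2, V2, M2, Fst, JostD, DAS, dmu2.
// [[Rcpp::export]]
NumericVector cpp_summary_stats(IntegerMatrix alleles, int n1, int n2) {
  const int L = alleles.ncol();
  const int c1 = 2 * n1, c2 = 2 * n2;
  if (alleles.nrow() != c1 + c2) stop("allele matrix / sample size mismatch");
  std::vector<int> col(c1 + c2);
  double A1 = 0, He1 = 0, V1 = 0, M1 = 0, A2 = 0, He2 = 0, V2 = 0, M2 = 0;
  double num_f = 0, den_f = 0, sumD = 0, dmu2 = 0;
  int nD = 0;
  const double nh = 2.0 / (1.0 / n1 + 1.0 / n2);

  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < c1 + c2; ++i) col[i] = alleles(i, l);
    PopLocus p1 = pop_locus(col.data(), c1);
    PopLocus p2 = pop_locus(col.data() + c1, c2);
    A1 += p1.A / L; A2 += p2.A / L;
    He1 += (c1 / (c1 - 1.0)) * (1.0 - p1.sump2) / L;
    He2 += (c2 / (c2 - 1.0)) * (1.0 - p2.sump2) / L;
    V1 += p1.var / L; V2 += p2.var / L;
    M1 += p1.A / (p1.range + 1.0) / L;
    M2 += p2.A / (p2.range + 1.0) / L;

    // Nei-Chesser Hs/Ht over the two samples
    const double hs_raw = 1.0 - (p1.sump2 + p2.sump2) / 2.0;
    const double hs = (2.0 * nh / (2.0 * nh - 1.0)) * hs_raw;
    // mean frequency vector: iterate distinct alleles of the pooled column
    std::vector<int> pool(col);
    std::sort(pool.begin(), pool.end());
    pool.erase(std::unique(pool.begin(), pool.end()), pool.end());
    double sbar2 = 0.0;
    for (int a : pool) {
      int k1 = 0, k2 = 0;
      for (int i = 0; i < c1; ++i) if (col[i] == a) ++k1;
      for (int i = c1; i < c1 + c2; ++i) if (col[i] == a) ++k2;
      const double pbar = ((double)k1 / c1 + (double)k2 / c2) / 2.0;
      sbar2 += pbar * pbar;
    }
    const double ht = (1.0 - sbar2) + hs / (4.0 * nh);
    if (ht > 0) { num_f += ht - hs; den_f += ht; }
    if (hs < 1.0 && ht > 0) { sumD += 2.0 * (ht - hs) / (1.0 - hs); ++nD; }

    // (delta mu)^2
    double m1 = 0, m2 = 0;
    for (int i = 0; i < c1; ++i) m1 += col[i];
    for (int i = c1; i < c1 + c2; ++i) m2 += col[i];
    m1 /= c1; m2 /= c2;
    dmu2 += (m1 - m2) * (m1 - m2) / L;
  }

  // mean shared-allele distance between populations
  double psa = 0.0;
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j) {
      double s = 0.0;
      for (int l = 0; l < L; ++l) {
        int a = alleles(2 * i, l), b = alleles(2 * i + 1, l);
        int c = alleles(c1 + 2 * j, l), d = alleles(c1 + 2 * j + 1, l);
        if (a > b) std::swap(a, b);
        if (c > d) std::swap(c, d);
        int sh;
        if (a == c && b == d) sh = 2;
        else if (a == c || a == d || b == c || b == d) sh = 1;
        else sh = 0;
        s += sh / 2.0;
      }
      psa += s / L;
    }
  const double das = 1.0 - psa / (n1 * (double)n2);

  NumericVector out(12);
  out[0] = A1; out[1] = He1; out[2] = V1; out[3] = M1;
  out[4] = A2; out[5] = He2; out[6] = V2; out[7] = M2;
  out[8] = (den_f > 0) ? num_f / den_f : 0.0;
  out[9] = (nD > 0) ? sumD / nD : 0.0;
  out[10] = das;
  out[11] = dmu2;
  return out;
}

// Build a block of reference-table records: simulate each (scenario, draw)
// and return its summary-statistic row.
// draws columns: N1, N2, Nanc, Nb, t1_gen, db_gen, mu, gsm_p, sni
// [[Rcpp::export]]
NumericMatrix cpp_reference_block(IntegerVector scenarios, NumericMatrix draws,
                                  int n1, int n2, int n_loci) {
  const int n = scenarios.size();
  if (draws.nrow() != n) stop("scenarios / draws mismatch");
  const int L0 = 2 * (n1 + n2);
  NumericMatrix out(n, 12);
  IntegerMatrix geno(L0, n_loci);
  std::vector<int> parent(2 * L0 - 1);
  std::vector<double> ntime(2 * L0 - 1), blen(2 * L0 - 1);
  std::vector<int> buf(L0);
  for (int r = 0; r < n; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    SimParams p{(int)scenarios[r], draws(r, 0), draws(r, 1), draws(r, 2),
                draws(r, 3), draws(r, 4), draws(r, 5), draws(r, 6),
                draws(r, 7), draws(r, 8)};
    if (p.t1 <= p.db) stop("invalid draw at record %d: t1 <= db", r + 1);
    for (int l = 0; l < n_loci; ++l) {
      sim_locus(p, n1, n2, buf.data(), parent, ntime, blen);
      for (int i = 0; i < L0; ++i) geno(i, l) = buf[i];
    }
    NumericVector s = cpp_summary_stats(geno, n1, n2);
    for (int j = 0; j < 12; ++j) out(r, j) = s[j];
  }
  return out;
}
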