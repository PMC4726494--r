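#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// JC69 pruning likelihood straight from the internal gene-tree
// representation (parent pointers + node times); the postorder is derived
// by sorting non-root nodes on their times, valid because child times are
// strictly below parent times.
// [[Rcpp::export(name = ".jc69_tree_cpp")]]
double jc69_tree_cpp(IntegerVector parent, NumericVector time, int nTip,
                     int root, double scalar, IntegerMatrix patterns,
                     NumericVector patWeight) {
  const int nNode = parent.size();
  const int P = patterns.ncol();
  std::vector<int> ord;
  ord.reserve(nNode - 1);
  for (int v = 1; v <= nNode; ++v) if (v != root) ord.push_back(v);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a - 1] < time[b - 1]; });

  std::vector<std::vector<double> > part(nNode + 1);
  for (int v = nTip + 1; v <= nNode; ++v) part[v].assign(4 * P, 1.0);
  for (int v = 1; v <= nTip; ++v) {
    part[v].assign(4 * P, 0.0);
    for (int s = 0; s < P; ++s) {
      int b = patterns(v - 1, s);
      if (b < 0) for (int x = 0; x < 4; ++x) part[v][4 * s + x] = 1.0;
      else part[v][4 * s + b] = 1.0;
    }
  }
  for (size_t k = 0; k < ord.size(); ++k) {
    int ch = ord[k];
    int par = parent[ch - 1];
    double t = (time[par - 1] - time[ch - 1]) * scalar;
    if (t < 0) t = 0;
    double ex = std::exp(-4.0 * t / 3.0);
    double pSame = 0.25 + 0.75 * ex, pDiff = 0.25 - 0.25 * ex;
    std::vector<double> &Lc = part[ch], &Lp = part[par];
    for (int s = 0; s < P; ++s) {
      double tot = Lc[4 * s] + Lc[4 * s + 1] + Lc[4 * s + 2] + Lc[4 * s + 3];
      for (int x = 0; x < 4; ++x)
        Lp[4 * s + x] *= pDiff * tot + (pSame - pDiff) * Lc[4 * s + x];
    }
  }
  double ll = 0.0;
  for (int s = 0; s < P; ++s) {
    double siteL = 0.25 * (part[root][4 * s] + part[root][4 * s + 1] +
                           part[root][4 * s + 2] + part[root][4 * s + 3]);
    ll += patWeight[s] * std::log(siteL);
  }
  return ll;
}

// Multispecies-coalescent log density of one gene tree on the fixed
// species tree ((T,N),E). ssCode per node: 0 = all-T, 1 = all-N, 2 = all-E,
// 3 = T+N mixture, 4 = contains E plus others. theta order:
// T, N, E, TN, TNE. Returns -Inf for trees violating the species tree.
// [[Rcpp::export(name = ".msc_density_cpp")]]
double msc_density_cpp(NumericVector time, IntegerVector ssCode, int nTip,
                       IntegerVector tipSpecies, double tauTN, double tauTNE,
                       NumericVector theta) {
  const int nNode = time.size();
  // population index: 0 T, 1 N, 2 E, 3 TN, 4 TNE
  std::vector<std::vector<double> > ev(5);
  for (int v = nTip + 1; v <= nNode; ++v) {
    double t = time[v - 1];
    int ss = ssCode[v - 1];
    int pop;
    if (t >= tauTNE) pop = 4;
    else if (t >= tauTN) {
      if (ss == 0 || ss == 1 || ss == 3) pop = 3;
      else if (ss == 2) pop = 2;
      else return R_NegInf;
    } else {
      if (ss >= 3) return R_NegInf;
      pop = ss;
    }
    ev[pop].push_back(t);
  }
  int nT = 0, nN = 0, nE = 0;
  for (int i = 0; i < nTip; ++i) {
    if (tipSpecies[i] == 0) ++nT;
    else if (tipSpecies[i] == 1) ++nN;
    else ++nE;
  }
  double lo[5] = {0, 0, 0, tauTN, tauTNE};
  double hi[5] = {tauTN, tauTN, tauTNE, tauTNE, R_PosInf};
  int enter[5];
  enter[0] = nT; enter[1] = nN; enter[2] = nE;
  enter[3] = (nT - (int)ev[0].size()) + (nN - (int)ev[1].size());
  enter[4] = (enter[3] - (int)ev[3].size()) + (nE - (int)ev[2].size());
  double ll = 0.0;
  for (int p = 0; p < 5; ++p) {
    int k = enter[p];
    int m = ev[p].size();
    if (m > std::max(0, k - 1)) return R_NegInf;
    if (p == 4 && m != k - 1) return R_NegInf;
    std::sort(ev[p].begin(), ev[p].end());
    double rate2 = 2.0 / theta[p];
    double tPrev = lo[p];
    for (int j = 0; j < m; ++j) {
      double te = ev[p][j];
      if (te < lo[p] - 1e-15 || te > hi[p]) return R_NegInf;
      ll += std::log(rate2) - k * (k - 1) / 2.0 * rate2 * (te - tPrev);
      tPrev = te;
      --k;
    }
    if (R_FINITE(hi[p]) && k >= 2)
      ll -= k * (k - 1) / 2.0 * rate2 * (hi[p] - tPrev);
  }
  return ll;
}
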