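#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Griffiths-Tavare sequential importance sampling under the infinite-sites
// coalescent. A sample configuration is a set of distinct haplotypes (each a
// list of segregating-site labels) with multiplicities. Backwards in time the
// admissible events are
//   * coalescence of two copies of the same haplotype, coefficient
//     n_i (n_i - 1) / 2, and
//   * removal of the most recent mutation: a site private to a haplotype of
//     multiplicity one, coefficient (theta/2) * n'_g where n'_g is the
//     multiplicity of the resulting haplotype after the removal (merged with
//     an existing identical type if one exists).
// Dividing the chosen move's coefficient sum by D = k(k-1+theta)/2 gives the
// importance weight of the Griffiths-Tavare proposal (events sampled
// proportionally to their recursion coefficients); the product of the factors
// over the history is an unbiased estimate of the sample probability.
// Conditional on the event sequence the holding times are Exp(D) at each
// step, so the genealogy height (TMRCA, coalescent units of N_f generations)
// is simulated alongside.

struct Move {
  int kind;    // 0 = coalescence, 1 = mutation removal
  int type;    // haplotype index
  int site;    // site removed (mutation moves)
  int mergeTo; // index of identical type after removal, -1 if none
  double coef;
};

// [[Rcpp::export(name = ".sis_run_cpp")]]
List sis_run_cpp(IntegerMatrix sites, IntegerVector mult, double theta,
                 int nParticles) {
  const int S = sites.nrow();
  const int K0 = sites.ncol();

  // initial haplotypes as sorted site lists
  std::vector<std::vector<int> > hap0(K0);
  for (int j = 0; j < K0; ++j)
    for (int s = 0; s < S; ++s)
      if (sites(s, j) == 1) hap0[j].push_back(s);

  std::vector<int> copies0(S, 0);   // sequence copies carrying each site
  for (int j = 0; j < K0; ++j)
    for (size_t a = 0; a < hap0[j].size(); ++a)
      copies0[hap0[j][a]] += mult[j];

  NumericVector logw(nParticles), height(nParticles);

  for (int p = 0; p < nParticles; ++p) {
    std::vector<std::vector<int> > hap = hap0;
    std::vector<int> m(mult.begin(), mult.end());
    std::vector<int> copies = copies0;
    double lw = 0.0, h = 0.0;
    int k = 0;
    for (int j = 0; j < (int)m.size(); ++j) k += m[j];

    while (k > 1) {
      std::vector<Move> moves;
      double sumc = 0.0;
      for (int i = 0; i < (int)hap.size(); ++i) {
        if (m[i] >= 2) {
          Move mv; mv.kind = 0; mv.type = i; mv.site = -1; mv.mergeTo = -1;
          mv.coef = 0.5 * m[i] * (m[i] - 1);
          moves.push_back(mv); sumc += mv.coef;
        }
        if (m[i] == 1 && theta > 0.0) {
          for (size_t a = 0; a < hap[i].size(); ++a) {
            int s = hap[i][a];
            if (copies[s] != 1) continue;   // not private to this lineage
            // haplotype after removing s
            std::vector<int> red;
            red.reserve(hap[i].size() - 1);
            for (size_t b = 0; b < hap[i].size(); ++b)
              if (hap[i][b] != s) red.push_back(hap[i][b]);
            int mergeTo = -1;
            for (int j = 0; j < (int)hap.size(); ++j)
              if (j != i && m[j] > 0 && hap[j] == red) { mergeTo = j; break; }
            Move mv; mv.kind = 1; mv.type = i; mv.site = s;
            mv.mergeTo = mergeTo;
            mv.coef = 0.5 * theta * (mergeTo >= 0 ? m[mergeTo] + 1 : 1);
            moves.push_back(mv); sumc += mv.coef;
          }
        }
      }
      const double D = 0.5 * k * (k - 1 + theta);
      if (moves.empty() || sumc <= 0.0) {
        lw = R_NegInf;           // incompatible with theta (e.g. theta = 0)
        break;
      }
      h += R::exp_rand() / D;    // holding time before this event
      lw += std::log(sumc) - std::log(D);

      double u = R::unif_rand() * sumc, acc = 0.0;
      int chosen = (int)moves.size() - 1;
      for (int q = 0; q < (int)moves.size(); ++q) {
        acc += moves[q].coef;
        if (u <= acc) { chosen = q; break; }
      }
      const Move &mv = moves[chosen];
      if (mv.kind == 0) {
        m[mv.type] -= 1;
        for (size_t a = 0; a < hap[mv.type].size(); ++a)
          copies[hap[mv.type][a]] -= 1;
        k -= 1;
      } else {
        copies[mv.site] = 0;
        if (mv.mergeTo >= 0) {
          m[mv.mergeTo] += 1;
          m[mv.type] = 0;
          hap[mv.type].clear();
        } else {
          std::vector<int> red;
          for (size_t b = 0; b < hap[mv.type].size(); ++b)
            if (hap[mv.type][b] != mv.site) red.push_back(hap[mv.type][b]);
          hap[mv.type] = red;
        }
      }
    }
    logw[p] = lw;
    height[p] = h;
  }
  return List::create(_["logw"] = logw, _["height"] = height);
}
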