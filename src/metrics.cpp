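#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Distributed-immunity metrics kernel.
//
// For each virus k and host i, let A_ik be the set of protospacer
// positions of k matched by a spacer of i. The triplet indicator for
// hosts (i, j) on virus k is 1 iff positions p != p' exist with p in A_ik
// and p' in A_jk, i.e. |A_ik| >= 1, |A_jk| >= 1 and not (both sets are
// the same single position). Only |A| and, when |A| == 1, the matched
// position are needed, so we accumulate counts via an inverted index
// spacer -> hosts carrying it (communities can hold thousands of viral
// strains; the per-host scan would be the bottleneck).

// [[Rcpp::export]]
NumericVector di_metrics_cpp(List host_spacers, NumericVector N,
                             List virus_protos, NumericVector V,
                             bool sigma_population) {
  const int nh = host_spacers.size();
  const int nv = virus_protos.size();

  std::unordered_map<int, std::vector<int> > carriers;
  for (int i = 0; i < nh; ++i) {
    IntegerVector g = host_spacers[i];
    for (int a : g) carriers[a].push_back(i);
  }

  double maxN = 0.0;
  for (int i = 0; i < nh; ++i) if (N[i] > maxN) maxN = N[i];

  auto sigma = [&](double ni, double nj) {
    double mx = sigma_population ? maxN : (ni > nj ? ni : nj);
    double d = ni > nj ? ni - nj : nj - ni;
    return 1.0 - d / mx;
  };

  double pdi = 0.0, idi = 0.0, hvi = 0.0;
  std::vector<int> cnt(nh, 0), last(nh, -1), active;
  active.reserve(nh);

  for (int k = 0; k < nv; ++k) {
    IntegerVector h = virus_protos[k];
    const int P = h.size();
    active.clear();
    for (int p = 0; p < P; ++p) {
      auto it = carriers.find(h[p]);
      if (it == carriers.end()) continue;
      for (int i : it->second) {
        if (cnt[i] == 0) active.push_back(i);
        ++cnt[i];
        last[i] = p;
      }
    }
    double vk = V[k], sumAct = 0.0;
    for (size_t ai = 0; ai < active.size(); ++ai) {
      int i = active[ai];
      idi += N[i] * vk * cnt[i];
      sumAct += N[i];
      for (size_t aj = ai + 1; aj < active.size(); ++aj) {
        int j = active[aj];
        if (cnt[i] == 1 && cnt[j] == 1 && last[i] == last[j]) continue;
        pdi += 2.0 * vk * N[i] * N[j] * sigma(N[i], N[j]);
      }
    }
    hvi += vk * (1.0 - sumAct); // hosts with no match
    for (int i : active) { cnt[i] = 0; last[i] = -1; }
  }

  // ceiling: every triplet contributing, viral proportions sum out
  double mp = 0.0;
  for (int i = 0; i < nh; ++i)
    for (int j = i + 1; j < nh; ++j)
      mp += N[i] * N[j] * sigma(N[i], N[j]);
  mp *= 2.0;

  return NumericVector::create(_["pdi"] = pdi, _["idi"] = idi,
                               _["hvi"] = hvi, _["max_pdi"] = mp);
}
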