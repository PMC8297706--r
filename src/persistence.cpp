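#include <Rcpp.h>
using namespace Rcpp;

// 0-dimensional superlevel-set persistence by union-find (elder rule).
//
// h:      non-negative heights per node.
// Ai, Ap: adjacency in compressed sparse column form, 0-based (pattern of a
//         structurally symmetric matrix; Ai[Ap[v]..Ap[v+1]-1] are the
//         neighbours of v).
// ord:    0-based processing order (height descending, index ascending on
//         ties); supplied by the caller so tie-breaking is pinned in one
//         place.
//
// Nodes are activated in order; each strict local maximum births a
// component at its height. When two components meet, the younger (lower
// birth; larger representative index on exact ties) dies at the current
// height; zero-persistence pairs (plateau artifacts) are discarded, so a
// flat plateau contributes a single peak. Components alive at the end are
// essential (death 0), one per connected component of the graph.
//
// Returns a list: birth, death, representative (1-based node index of the
// component's maximum), essential flag.
// [[Rcpp::export]]
List persistence_cpp(NumericVector h, IntegerVector Ai, IntegerVector Ap,
                     IntegerVector ord) {
  const int n = h.size();
  if (ord.size() != n) stop("order must cover all nodes");
  std::vector<int> parent(n, -1);   // -1 = not yet activated
  std::vector<int> repv(n, -1);     // representative (birth vertex) at root

  std::vector<double> births, deaths;
  std::vector<int> reps;

  auto find = [&](int v) {
    while (parent[v] != v) {
      parent[v] = parent[parent[v]];
      v = parent[v];
    }
    return v;
  };

  for (int k = 0; k < n; ++k) {
    const int v = ord[k];
    if (v < 0 || v >= n) stop("order index out of range");
    parent[v] = v;
    repv[v] = v;
    const double hv = h[v];
    for (int q = Ap[v]; q < Ap[v + 1]; ++q) {
      const int u = Ai[q];
      if (u == v || parent[u] < 0) continue;  // self-loop or inactive
      int ru = find(u);
      int rv = find(v);
      if (ru == rv) continue;
      // elder: higher birth; tie -> smaller representative index
      int elder, younger;
      const double bu = h[repv[ru]], bv = h[repv[rv]];
      if (bu > bv || (bu == bv && repv[ru] < repv[rv])) {
        elder = ru; younger = rv;
      } else {
        elder = rv; younger = ru;
      }
      const double by = h[repv[younger]];
      if (by > hv) {  // drop zero-persistence plateau pairs
        births.push_back(by);
        deaths.push_back(hv);
        reps.push_back(repv[younger] + 1);
      }
      parent[younger] = elder;
    }
  }

  // essential classes: surviving roots
  std::vector<double> ebirths;
  std::vector<int> ereps;
  for (int v = 0; v < n; ++v) {
    if (parent[v] == v) {
      ebirths.push_back(h[repv[v]]);
      ereps.push_back(repv[v] + 1);
    }
  }
  const int nf = births.size(), ne = ebirths.size();
  NumericVector birth(nf + ne), death(nf + ne);
  IntegerVector rep(nf + ne);
  LogicalVector ess(nf + ne);
  for (int i = 0; i < ne; ++i) {
    birth[i] = ebirths[i]; death[i] = 0.0; rep[i] = ereps[i]; ess[i] = true;
  }
  for (int i = 0; i < nf; ++i) {
    birth[ne + i] = births[i]; death[ne + i] = deaths[i];
    rep[ne + i] = reps[i]; ess[ne + i] = false;
  }
  return List::create(_["birth"] = birth, _["death"] = death,
                      _["representative"] = rep, _["essential"] = ess);
}
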