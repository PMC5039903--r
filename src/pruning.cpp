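#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns, mixed over
// equal-weight discrete-gamma rate categories.
//
// edge:      nEdge x 2 integer matrix (parent, child), 1-based node ids,
//            listed in postorder (every child edge before its parent's).
// tipStates: nTip x nPat integer matrix, 0..3 = A,C,G,T; -1 = missing
//            (treated as an uninformative tip).
// P:         numeric vector of length 16 * nEdge * nCat laid out as
//            [i + 4*j + 16*e + 16*nEdge*c] = P(parent state i -> child j)
//            on edge e under category c.
// pi:        root (equilibrium) frequencies, length 4.
// weights:   pattern multiplicities, length nPat.
// nNode:     total number of nodes (tips + internals).
// root:      1-based id of the root node.
// [[Rcpp::export(name = ".pruningLogLik")]]
double pruningLogLik(IntegerMatrix edge, IntegerMatrix tipStates,
                     NumericVector P, NumericVector pi,
                     NumericVector weights, int nNode, int root, int nCat) {
  const int nEdge = edge.nrow();
  const int nTip = tipStates.nrow();
  const int nPat = tipStates.ncol();
  std::vector<double> part(4 * nNode);
  std::vector<double> siteL(nPat, 0.0);
  const double catW = 1.0 / nCat;

  for (int c = 0; c < nCat; ++c) {
    const double *Pc = REAL(P) + (size_t)16 * nEdge * c;
    for (int s = 0; s < nPat; ++s) {
      // initialise partials: tips = indicators, internals = 1
      for (int n = 0; n < nNode; ++n) {
        double *pn = &part[4 * n];
        if (n < nTip) {
          int st = tipStates(n, s);
          if (st < 0) { pn[0] = pn[1] = pn[2] = pn[3] = 1.0; }
          else {
            pn[0] = pn[1] = pn[2] = pn[3] = 0.0;
            pn[st] = 1.0;
          }
        } else {
          pn[0] = pn[1] = pn[2] = pn[3] = 1.0;
        }
      }
      for (int e = 0; e < nEdge; ++e) {
        int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
        const double *Pe = Pc + (size_t)16 * e;
        const double *pc_ = &part[4 * ch];
        double *pp = &part[4 * par];
        for (int i = 0; i < 4; ++i) {
          double sum = 0.0;
          for (int j = 0; j < 4; ++j) sum += Pe[i + 4 * j] * pc_[j];
          pp[i] *= sum;
        }
      }
      const double *pr = &part[4 * (root - 1)];
      double L = 0.0;
      for (int i = 0; i < 4; ++i) L += pi[i] * pr[i];
      siteL[s] += catW * L;
    }
  }
  double ll = 0.0;
  for (int s = 0; s < nPat; ++s) {
    if (siteL[s] <= 0.0) return R_NegInf;
    ll += weights[s] * std::log(siteL[s]);
  }
  return ll;
}
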