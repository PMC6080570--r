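#include <Rcpp.h>
using namespace Rcpp;

// Kernels for nearest-taxon phylogenetic statistics. D is the taxa x taxa
// patristic distance matrix; W is the samples x taxa abundance (or 0/1
// presence) matrix aligned with D; perm is a 0-based permutation of taxon
// indices applied to D, which is how tip-label shuffling is realised without
// copying D.

// Weighted mean nearest-taxon distance within each sample. Weights are
// normalised over present taxa; pass 0/1 presence for the unweighted
// statistic. Samples with fewer than two present taxa yield NA.
// [[Rcpp::export]]
NumericVector cpp_mntd(NumericMatrix D, NumericMatrix W, IntegerVector perm) {
  int n = W.nrow(), t = W.ncol();
  NumericVector out(n);
  std::vector<int> pres;
  pres.reserve(t);
  for (int s = 0; s < n; ++s) {
    pres.clear();
    double wtot = 0.0;
    for (int i = 0; i < t; ++i)
      if (W(s, i) > 0) { pres.push_back(i); wtot += W(s, i); }
    int np = pres.size();
    if (np < 2) { out[s] = NA_REAL; continue; }
    double acc = 0.0;
    for (int a = 0; a < np; ++a) {
      int pi = perm[pres[a]];
      double best = R_PosInf;
      for (int b = 0; b < np; ++b) {
        if (b == a) continue;
        double d = D(pi, perm[pres[b]]);
        if (d < best) best = d;
      }
      acc += W(s, pres[a]) / wtot * best;
    }
    out[s] = acc;
  }
  return out;
}

// Pairwise weighted beta mean nearest-taxon distance:
// bMNTD(A,B) = 0.5 * [ sum_{i in A} f_iA min_{j in B} d(i,j)
//                    + sum_{j in B} f_jB min_{i in A} d(i,j) ]
// with f the within-sample relative weights. For each sample the vector of
// nearest distances from every taxon to that sample is computed once, so the
// whole matrix costs O(n*t*richness + n^2*t).
// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd(NumericMatrix D, NumericMatrix W, IntegerVector perm) {
  int n = W.nrow(), t = W.ncol();
  std::vector< std::vector<int> > pres(n);
  std::vector<double> wtot(n, 0.0);
  for (int s = 0; s < n; ++s) {
    pres[s].reserve(t);
    for (int i = 0; i < t; ++i)
      if (W(s, i) > 0) { pres[s].push_back(i); wtot[s] += W(s, i); }
    if (pres[s].empty()) stop("sample with no taxa present");
  }
  // gmin(s, i): distance from taxon i to its nearest member of sample s
  NumericMatrix gmin(n, t);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < t; ++i) {
      int pi = perm[i];
      double best = R_PosInf;
      for (size_t b = 0; b < pres[s].size(); ++b) {
        double d = D(pi, perm[pres[s][b]]);
        if (d < best) best = d;
      }
      gmin(s, i) = best;
    }
  }
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double accA = 0.0, accB = 0.0;
      for (size_t k = 0; k < pres[a].size(); ++k) {
        int i = pres[a][k];
        accA += W(a, i) / wtot[a] * gmin(b, i);
      }
      for (size_t k = 0; k < pres[b].size(); ++k) {
        int j = pres[b][k];
        accB += W(b, j) / wtot[b] * gmin(a, j);
      }
      out(a, b) = out(b, a) = 0.5 * (accA + accB);
    }
  }
  return out;
}
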