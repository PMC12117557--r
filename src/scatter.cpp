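#include <Rcpp.h>
using namespace Rcpp;

// Weighted scatter-add over edges: S[tgt[e], ] += w[e] * H[src[e], ].
// This is the inner kernel of the normalized-adjacency product in the GCN
// forward and backward passes; indices are 1-based (R convention).
// [[Rcpp::export(name = ".gcn_scatter")]]
NumericMatrix gcn_scatter(NumericMatrix H, IntegerVector src,
                          IntegerVector tgt, NumericVector w, int N) {
  const int C = H.ncol(), E = src.size(), nH = H.nrow();
  NumericMatrix S(N, C);
  const double *h = REAL(H), *wp = REAL(w);
  double *s = REAL(S);
  const int *sp = INTEGER(src), *tp = INTEGER(tgt);
  for (int e = 0; e < E; ++e) {
    if (sp[e] < 1 || sp[e] > nH || tp[e] < 1 || tp[e] > N)
      stop("edge index out of range");
  }
  for (int c = 0; c < C; ++c) {
    const double *hc = h + (size_t)c * nH;
    double *sc = s + (size_t)c * N;
    for (int e = 0; e < E; ++e) sc[tp[e] - 1] += wp[e] * hc[sp[e] - 1];
  }
  return S;
}

// Fused bias-add + ReLU: out = max(M + b (per column), 0).
// [[Rcpp::export(name = ".bias_relu")]]
NumericMatrix bias_relu(NumericMatrix M, NumericVector b) {
  const int n = M.nrow(), C = M.ncol();
  if (b.size() != C) stop("bias length mismatch");
  NumericMatrix out(n, C);
  const double *m = REAL(M), *bp = REAL(b);
  double *o = REAL(out);
  for (int c = 0; c < C; ++c) {
    const double bc = bp[c];
    const double *mc = m + (size_t)c * n;
    double *oc = o + (size_t)c * n;
    for (int i = 0; i < n; ++i) {
      double v = mc[i] + bc;
      oc[i] = v > 0 ? v : 0;
    }
  }
  return out;
}
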