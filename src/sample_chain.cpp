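#include <Rcpp.h>
using namespace Rcpp;

// Sequentially sample a base sequence from an order-k Markov chain.
// trans: 4^order x 4 row-stochastic matrix, rows ordered by left k-mer code.
// u: pre-generated uniforms (length = sequence length), so determinism is
// inherited from R's RNG. gcProb: optional per-position target G+C
// probability (length 0 disables modulation); when present, the chain's
// emission row is reweighted so that P(G or C) equals gcProb[i], keeping
// within-class proportions (even split if the class has no chain mass).
// Returns base codes 1..4. The first `order` bases are drawn uniformly
// (burn-in is negligible at the intended Mb scale).
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix trans, int order,
                               NumericVector u, NumericVector gcProb) {
  const int L = u.size();
  IntegerVector out(L);
  const int nctx = trans.nrow();
  const bool gc = gcProb.size() > 0;
  int ctx = 0;
  for (int i = 0; i < L; ++i) {
    double p[4];
    if (i < order) {
      p[0] = p[1] = p[2] = p[3] = 0.25;
    } else {
      for (int b = 0; b < 4; ++b) p[b] = trans(ctx, b);
    }
    if (gc) {
      const double g = gcProb[i];
      const double pGC = p[1] + p[2];   // C + G
      const double pAT = p[0] + p[3];   // A + T
      double q[4];
      if (pGC > 0) { q[1] = g * p[1] / pGC; q[2] = g * p[2] / pGC; }
      else         { q[1] = q[2] = g / 2.0; }
      if (pAT > 0) { q[0] = (1 - g) * p[0] / pAT; q[3] = (1 - g) * p[3] / pAT; }
      else         { q[0] = q[3] = (1 - g) / 2.0; }
      for (int b = 0; b < 4; ++b) p[b] = q[b];
    }
    const double uu = u[i];
    double c = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) { c += p[j]; if (uu < c) { b = j; break; } }
    out[i] = b + 1;
    if (order > 0) ctx = (ctx * 4 + b) % nctx;
  }
  return out;
}
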