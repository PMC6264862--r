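#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweeps for LDA. Token i in document doc[i] carries
// vocabulary item word[i] (both 0-based here); z holds current topic
// assignments (0-based). Count tables njk (J x K), nkg (K x G) and nk
// (K) are updated in place; the full conditional for a token is
// proportional to (njk + alpha) * (nkg + eta) / (nk + G * eta).
// Uses R's RNG so chains are reproducible from set.seed().
// [[Rcpp::export]]
void lda_gibbs_sweeps(IntegerVector doc, IntegerVector word,
                      IntegerVector z, IntegerMatrix njk,
                      IntegerMatrix nkg, IntegerVector nk,
                      double alpha, double eta, int n_sweeps) {
  const int n = doc.size();
  const int K = nk.size();
  const int G = nkg.ncol();
  const double Geta = G * eta;
  std::vector<double> p(K);
  RNGScope scope;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      const int j = doc[i], g = word[i], k_old = z[i];
      --njk(j, k_old);
      --nkg(k_old, g);
      --nk[k_old];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (njk(j, k) + alpha) * (nkg(k, g) + eta) / (nk[k] + Geta);
        p[k] = tot;
      }
      const double u = unif_rand() * tot;
      int k_new = 0;
      while (k_new < K - 1 && p[k_new] < u) ++k_new;
      ++njk(j, k_new);
      ++nkg(k_new, g);
      ++nk[k_new];
      z[i] = k_new;
    }
  }
}
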