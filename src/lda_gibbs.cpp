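#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA with symmetric Dirichlet priors.
// docs: list of 0-based integer word-id vectors. Uses R's RNG, so results
// are controlled by set.seed() on the R side.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double beta,
                   int n_iter) {
  int D = docs.size();
  std::vector< std::vector<int> > w(D), z(D);
  std::vector< std::vector<int> > nwk(K, std::vector<int>(V, 0));
  std::vector< std::vector<int> > ndk(D, std::vector<int>(K, 0));
  std::vector<int> nk(K, 0);

  RNGScope scope;
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    int Nd = doc.size();
    w[d].assign(doc.begin(), doc.end());
    z[d].resize(Nd);
    for (int i = 0; i < Nd; ++i) {
      int k = (int)(unif_rand() * K);
      if (k >= K) k = K - 1;
      z[d][i] = k;
      ++nwk[k][w[d][i]];
      ++ndk[d][k];
      ++nk[k];
    }
  }

  std::vector<double> p(K);
  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      int Nd = (int)w[d].size();
      for (int i = 0; i < Nd; ++i) {
        int wi = w[d][i];
        int k = z[d][i];
        --nwk[k][wi]; --ndk[d][k]; --nk[k];
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          p[kk] = (nwk[kk][wi] + beta) / (nk[kk] + V * beta)
                  * (ndk[d][kk] + alpha);
          tot += p[kk];
        }
        double u = unif_rand() * tot, c = 0.0;
        int knew = K - 1;
        for (int kk = 0; kk < K; ++kk) {
          c += p[kk];
          if (u <= c) { knew = kk; break; }
        }
        z[d][i] = knew;
        ++nwk[knew][wi]; ++ndk[d][knew]; ++nk[knew];
      }
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v)
      phi(k, v) = (nwk[k][v] + beta) / (nk[k] + V * beta);
  for (int d = 0; d < D; ++d) {
    int Nd = (int)w[d].size();
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[d][k] + alpha) / (Nd + K * alpha);
  }
  return List::create(_["phi"] = phi, _["theta"] = theta);
}
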