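// Collapsed Gibbs sampler for latent Dirichlet allocation over locus-pair
// "words". Uses a privately seeded mt19937 so results are reproducible and
// independent of R's RNG state. Counts are kept in flat int arrays and the
// per-topic denominators as incrementally maintained reciprocals, so the
// inner loop is multiply-only.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// docs: list of integer matrices with columns (word_id 0-based, count)
// [[Rcpp::export]]
arma::mat lda_gibbs(const List &docs, int n_vocab, int n_topics, double alpha,
                    double beta, int iters, int seed) {
  const int D = docs.size();
  std::vector<int> tok_doc, tok_word;
  for (int d = 0; d < D; ++d) {
    IntegerMatrix m = docs[d];
    for (int r = 0; r < m.nrow(); ++r)
      for (int c = 0; c < m(r, 1); ++c) {
        tok_doc.push_back(d);
        tok_word.push_back(m(r, 0));
      }
  }
  const size_t n_tok = tok_doc.size();
  const int K = n_topics;
  std::vector<int> ndk(static_cast<size_t>(D) * K, 0);
  std::vector<int> nkw(static_cast<size_t>(n_vocab) * K, 0); // word-major
  std::vector<int> nk(K, 0);
  std::vector<int> z(n_tok);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (size_t t = 0; t < n_tok; ++t) {
    int k = static_cast<int>(unif(rng) * K);
    if (k == K) k = K - 1;
    z[t] = k;
    ndk[static_cast<size_t>(tok_doc[t]) * K + k]++;
    nkw[static_cast<size_t>(tok_word[t]) * K + k]++;
    nk[k]++;
  }
  const double vbeta = n_vocab * beta;
  std::vector<double> invnk(K);
  for (int k = 0; k < K; ++k) invnk[k] = 1.0 / (nk[k] + vbeta);
  std::vector<double> p(K);
  for (int it = 0; it < iters; ++it) {
    for (size_t t = 0; t < n_tok; ++t) {
      int *nd = &ndk[static_cast<size_t>(tok_doc[t]) * K];
      int *nw = &nkw[static_cast<size_t>(tok_word[t]) * K];
      const int old = z[t];
      nd[old]--;
      nw[old]--;
      nk[old]--;
      invnk[old] = 1.0 / (nk[old] + vbeta);
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (nd[k] + alpha) * (nw[k] + beta) * invnk[k];
        tot += p[k];
      }
      double u = unif(rng) * tot, acc = 0.0;
      int k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        acc += p[kk];
        if (u <= acc) {
          k = kk;
          break;
        }
      }
      z[t] = k;
      nd[k]++;
      nw[k]++;
      nk[k]++;
      invnk[k] = 1.0 / (nk[k] + vbeta);
    }
  }
  arma::mat theta(D, K);
  for (int d = 0; d < D; ++d) {
    double ndtot = 0;
    for (int k = 0; k < K; ++k) ndtot += ndk[static_cast<size_t>(d) * K + k];
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[static_cast<size_t>(d) * K + k] + alpha) /
        (ndtot + K * alpha);
  }
  return theta;
}
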