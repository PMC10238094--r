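#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA on a binarized accessibility matrix.
// Tokens are the nonzero (cell, region) entries; documents are cells and
// the vocabulary is the region set. theta/phi are posterior point
// estimates from the final sweep's counts.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_words, int n_topics,
                   double alpha, double beta, int n_iter,
                   unsigned int seed) {
  const int N = doc.size();
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(N);
  std::vector<int> ndt((size_t)n_docs * n_topics, 0);
  std::vector<int> nwt((size_t)n_words * n_topics, 0);
  std::vector<int> nt(n_topics, 0);
  std::vector<int> nd(n_docs, 0);

  for (int i = 0; i < N; ++i) {
    int t = (int)(unif(rng) * n_topics);
    if (t == n_topics) t = n_topics - 1;
    z[i] = t;
    ndt[(size_t)doc[i] * n_topics + t]++;
    nwt[(size_t)word[i] * n_topics + t]++;
    nt[t]++;
    nd[doc[i]]++;
  }

  NumericVector ll_trace(n_iter);
  std::vector<double> p(n_topics);
  const double wbeta = n_words * beta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i], told = z[i];
      ndt[(size_t)d * n_topics + told]--;
      nwt[(size_t)w * n_topics + told]--;
      nt[told]--;
      double tot = 0.0;
      for (int t = 0; t < n_topics; ++t) {
        p[t] = (ndt[(size_t)d * n_topics + t] + alpha) *
               (nwt[(size_t)w * n_topics + t] + beta) / (nt[t] + wbeta);
        tot += p[t];
      }
      double u = unif(rng) * tot, acc = 0.0;
      int tnew = n_topics - 1;
      for (int t = 0; t < n_topics; ++t) {
        acc += p[t];
        if (u <= acc) { tnew = t; break; }
      }
      z[i] = tnew;
      ndt[(size_t)d * n_topics + tnew]++;
      nwt[(size_t)w * n_topics + tnew]++;
      nt[tnew]++;
    }
    // joint log-likelihood (word part + doc part), up to constants shared
    // across iterations
    double ll = 0.0;
    for (int t = 0; t < n_topics; ++t) {
      for (int w = 0; w < n_words; ++w)
        ll += std::lgamma(nwt[(size_t)w * n_topics + t] + beta);
      ll -= std::lgamma(nt[t] + wbeta);
    }
    for (int d = 0; d < n_docs; ++d) {
      for (int t = 0; t < n_topics; ++t)
        ll += std::lgamma(ndt[(size_t)d * n_topics + t] + alpha);
      ll -= std::lgamma(nd[d] + n_topics * alpha);
    }
    ll_trace[iter] = ll;
  }

  NumericMatrix theta(n_docs, n_topics);
  for (int d = 0; d < n_docs; ++d)
    for (int t = 0; t < n_topics; ++t)
      theta(d, t) = (ndt[(size_t)d * n_topics + t] + alpha) /
                    (nd[d] + n_topics * alpha);
  NumericMatrix phi(n_topics, n_words);
  for (int t = 0; t < n_topics; ++t)
    for (int w = 0; w < n_words; ++w)
      phi(t, w) = (nwt[(size_t)w * n_topics + t] + beta) / (nt[t] + wbeta);

  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["log_likelihood_trace"] = ll_trace);
}
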