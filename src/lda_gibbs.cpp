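#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation over a token
// stream. docIdx/wordIdx are 0-based per-token indices. Returns the final
// count matrices; the R wrapper applies Dirichlet smoothing and
// normalization. Uses R's RNG stream, so the caller seeds via set.seed.

// [[Rcpp::export(name = "ldaGibbs")]]
List ldaGibbs(IntegerVector docIdx, IntegerVector wordIdx, int nDocs,
              int nWords, int nTopics, int iterations, double alpha,
              double beta) {
  const int nTokens = docIdx.size();
  RNGScope scope;

  IntegerMatrix topicWord(nTopics, nWords);
  IntegerMatrix docTopic(nDocs, nTopics);
  IntegerVector topicTotal(nTopics);
  IntegerVector z(nTokens);

  // random initialization
  for (int i = 0; i < nTokens; ++i) {
    int t = (int)(unif_rand() * nTopics);
    if (t == nTopics) t = nTopics - 1;
    z[i] = t;
    ++topicWord(t, wordIdx[i]);
    ++docTopic(docIdx[i], t);
    ++topicTotal[t];
  }

  std::vector<double> prob(nTopics);
  const double wBeta = nWords * beta;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < nTokens; ++i) {
      const int d = docIdx[i], w = wordIdx[i], told = z[i];
      --topicWord(told, w);
      --docTopic(d, told);
      --topicTotal[told];
      double total = 0.0;
      for (int t = 0; t < nTopics; ++t) {
        double p = (topicWord(t, w) + beta) / (topicTotal[t] + wBeta) *
                   (docTopic(d, t) + alpha);
        prob[t] = p;
        total += p;
      }
      double u = unif_rand() * total;
      int tnew = 0;
      double acc = prob[0];
      while (u > acc && tnew < nTopics - 1) acc += prob[++tnew];
      z[i] = tnew;
      ++topicWord(tnew, w);
      ++docTopic(d, tnew);
      ++topicTotal[tnew];
    }
  }
  return List::create(_["topicWord"] = topicWord, _["docTopic"] = docTopic);
}
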