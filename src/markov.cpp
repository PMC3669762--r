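#include <Rcpp.h>
using namespace Rcpp;

// Sample one sequence from an order-m Markov chain over {A,C,G,T} codes
// 0..3. cum_prob holds cumulative conditional probabilities, one row per
// context (4^order rows; contexts indexed with the oldest base as the most
// significant base-4 digit). init supplies the first `order` base codes.
// Draws come from R's RNG, so results are governed by set.seed().
// [[Rcpp::export]]
IntegerVector markov_chain_sample(NumericMatrix cum_prob, int order, int len,
                                  IntegerVector init) {
  IntegerVector out(len);
  int nctx1 = 1;
  for (int i = 0; i < order - 1; ++i) nctx1 *= 4;
  int pos = 0;
  int upfront = std::min(order, len);
  for (; pos < upfront; ++pos) out[pos] = init[pos];
  int ctx = 0;
  for (int i = 0; i < upfront; ++i) ctx = ctx * 4 + out[i];
  for (; pos < len; ++pos) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > cum_prob(ctx, b)) ++b;
    out[pos] = b;
    if (order > 0) ctx = (ctx % nctx1) * 4 + b;
  }
  return out;
}
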