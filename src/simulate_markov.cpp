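#include <Rcpp.h>
using namespace Rcpp;

// Simulate a fixed-order Markov chain over {A,C,G,T}.
//
// trans: (4^order) x 4 row-stochastic matrix; rows are contexts in
//        lexicographic order (AA, AC, AG, AT, CA, ... for order 2).
// init:  length-4 distribution used i.i.d. for the first `order` bases.
//
// Draws come from R's RNG (unif_rand), so results are reproducible
// under set.seed() and respect the caller's RNG state.
// [[Rcpp::export]]
std::string simulate_markov_cpp(NumericMatrix trans, int order, int len,
                                NumericVector init) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  if (order < 0) stop("order must be >= 0");
  const int ncontext = trans.nrow();
  if (trans.ncol() != 4 || init.size() != 4)
    stop("trans must have 4 columns and init length 4");
  std::string out(static_cast<size_t>(len), 'A');
  int ctx = 0;
  for (int i = 0; i < len; ++i) {
    const double u = unif_rand();
    double row[4];
    if (i < order) {
      for (int b = 0; b < 4; ++b) row[b] = init[b];
    } else {
      for (int b = 0; b < 4; ++b) row[b] = trans(ctx, b);
    }
    int b = 0;
    double acc = row[0];
    while (b < 3 && u > acc) acc += row[++b];
    out[static_cast<size_t>(i)] = alpha[b];
    if (order > 0) ctx = (ctx * 4 + b) % ncontext;
  }
  return out;
}
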