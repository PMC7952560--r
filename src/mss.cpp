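#include <Rcpp.h>
using namespace Rcpp;

// Ma-Sandri-Sarkar probability recursion for the Luria-Delbrück mutant-count
// distribution: p_0 = exp(-m), p_r = (m/r) * sum_{i=0}^{r-1} p_i / (r - i + 1).
// O(r_max^2); r_max is bounded by the jackpot cap upstream.
// [[Rcpp::export(name = ".ld_pmf_cpp")]]
NumericVector ld_pmf_cpp(double m, int r_max) {
  NumericVector p(r_max + 1);
  p[0] = std::exp(-m);
  for (int r = 1; r <= r_max; ++r) {
    double s = 0.0;
    for (int i = 0; i < r; ++i) s += p[i] / (double)(r - i + 1);
    p[r] = (m / (double)r) * s;
  }
  return p;
}
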