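#include <Rcpp.h>
using namespace Rcpp;

// Weighted pool-adjacent-violators: least-squares nondecreasing fit.
// Stack algorithm; O(n) amortized. Weights must be strictly positive
// (checked on the R side).
// [[Rcpp::export(name = ".pava_cpp")]]
NumericVector pava_cpp(NumericVector y, NumericVector w) {
  const int n = y.size();
  NumericVector out(n);
  if (n == 0) return out;

  std::vector<double> level(n), weight(n);
  std::vector<int> len(n);
  int top = -1;

  for (int i = 0; i < n; ++i) {
    ++top;
    level[top] = y[i];
    weight[top] = w[i];
    len[top] = 1;
    while (top > 0 && level[top - 1] > level[top]) {
      double wsum = weight[top - 1] + weight[top];
      level[top - 1] = (weight[top - 1] * level[top - 1] +
                        weight[top] * level[top]) / wsum;
      weight[top - 1] = wsum;
      len[top - 1] += len[top];
      --top;
    }
  }

  int pos = 0;
  for (int b = 0; b <= top; ++b)
    for (int j = 0; j < len[b]; ++j)
      out[pos++] = level[b];
  return out;
}
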