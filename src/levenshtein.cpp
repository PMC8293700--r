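#include <Rcpp.h>
using namespace Rcpp;

// Core DP on code-point vectors. Strings are decoded to integer code points
// on the R side (utf8ToInt) so multibyte characters count as one edit unit.
static int lev_core(const int *a, int na, const int *b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export]]
IntegerVector lev_pairs_cpp(List xs, List ys) {
  int n = xs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = xs[i];
    IntegerVector b = ys[i];
    out[i] = lev_core(a.begin(), a.size(), b.begin(), b.size());
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix lev_cross_cpp(List xs, List ys) {
  int nx = xs.size(), ny = ys.size();
  IntegerMatrix out(nx, ny);
  std::vector<std::vector<int>> bx(ny);
  for (int j = 0; j < ny; ++j) {
    IntegerVector b = ys[j];
    bx[j].assign(b.begin(), b.end());
  }
  for (int i = 0; i < nx; ++i) {
    IntegerVector a = xs[i];
    std::vector<int> av(a.begin(), a.end());
    for (int j = 0; j < ny; ++j) {
      out(i, j) = lev_core(av.data(), av.size(), bx[j].data(), bx[j].size());
    }
  }
  return out;
}
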