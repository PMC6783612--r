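#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Floyd–Warshall on a dense length matrix held row-major in d (n x n).
// Dense FA connectomes have ~2/3 of all pairs connected, so the cubic
// dense sweep beats heap-based Dijkstra here.
static void floyd_warshall(std::vector<double>& d, int n) {
  for (int k = 0; k < n; ++k) {
    const double* dk = &d[(size_t)k * n];
    for (int i = 0; i < n; ++i) {
      const double dik = d[(size_t)i * n + k];
      if (!std::isfinite(dik)) continue;
      double* di = &d[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        const double alt = dik + dk[j];
        if (alt < di[j]) di[j] = alt;
      }
    }
  }
}

static double efficiency_from_lengths(std::vector<double>& d, int n) {
  floyd_warshall(d, n);
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && std::isfinite(d[(size_t)i * n + j]) && d[(size_t)i * n + j] > 0)
        s += 1.0 / d[(size_t)i * n + j];
  return s / ((double)n * (n - 1));
}

// [[Rcpp::export]]
NumericVector local_efficiency_dense(NumericMatrix W, bool binary) {
  const int n = W.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  std::vector<int> nb;
  nb.reserve(n);
  std::vector<double> d;
  for (int v = 0; v < n; ++v) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != v && W(v, j) > 0) nb.push_back(j);
    const int m = (int)nb.size();
    if (m < 2) { out[v] = 0.0; continue; }
    d.assign((size_t)m * m, inf);
    for (int a = 0; a < m; ++a) {
      d[(size_t)a * m + a] = 0.0;
      for (int b = a + 1; b < m; ++b) {
        const double w = W(nb[a], nb[b]);
        if (w > 0) {
          const double len = binary ? 1.0 : 1.0 / w;
          d[(size_t)a * m + b] = len;
          d[(size_t)b * m + a] = len;
        }
      }
    }
    out[v] = efficiency_from_lengths(d, m);
  }
  return out;
}

// [[Rcpp::export]]
double global_efficiency_dense(NumericMatrix W, bool binary) {
  const int n = W.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d((size_t)n * n, inf);
  for (int i = 0; i < n; ++i) {
    d[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      const double w = W(i, j);
      if (w > 0) {
        const double len = binary ? 1.0 : 1.0 / w;
        d[(size_t)i * n + j] = len;
        d[(size_t)j * n + i] = len;
      }
    }
  }
  return efficiency_from_lengths(d, n);
}
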