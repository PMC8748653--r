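#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// reflect index i into [0, n-1] (symmetric padding, edge not repeated twice
// for interior-sized windows; degenerates safely for n == 1)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector median_filter3_cpp(NumericVector x, IntegerVector dim,
                                 IntegerVector window) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int wz = window[0] / 2, wy = window[1] / 2, wx = window[2] / 2;
  NumericVector out(x.size());
  std::vector<double> buf;
  buf.reserve((size_t)(2 * wz + 1) * (2 * wy + 1) * (2 * wx + 1));
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) {
        buf.clear();
        for (int dk = -wx; dk <= wx; ++dk) {
          int kk = reflect(k + dk, nx);
          for (int dj = -wy; dj <= wy; ++dj) {
            int jj = reflect(j + dj, ny);
            for (int di = -wz; di <= wz; ++di) {
              int ii = reflect(i + di, nz);
              buf.push_back(x[ii + (size_t)nz * (jj + (size_t)ny * kk)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[i + (size_t)nz * (j + (size_t)ny * k)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 3D connected-component labelling of a logical mask; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components3_cpp(LogicalVector mask, IntegerVector dim,
                                    int connectivity = 26) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < (size_t)mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t v = q.front(); q.pop();
      int i = v % nz, j = (v / nz) % ny, k = v / ((size_t)nz * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) > 1)
              continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nz || jj < 0 || jj >= ny || kk < 0 || kk >= nx)
              continue;
            size_t w = ii + (size_t)nz * (jj + (size_t)ny * kk);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              q.push(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
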