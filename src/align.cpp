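// Exact global alignment minimizing the lattice obfuscation distance.
//
// Substitution cost of a column is the lattice distance of its two
// symbols; a residue aligned against an inserted gap costs its lattice
// distance to "-". Tie-breaking in the traceback is fixed: diagonal,
// then up (x residue vs gap), then left (gap vs y residue), so the
// alignment is fully deterministic. An optional band restricts the DP
// to cells with |i - j| <= band + |n - m|; with band <= 0 the full
// matrix is computed (always exact).

#include <Rcpp.h>
#include <climits>
#include <cctype>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int BIG = INT_MAX / 4;

// [[Rcpp::export(name = ".alignCoreCpp")]]
List alignCoreCpp(std::string x, std::string y, IntegerMatrix cost,
                  std::string alphabet, int gapIndex, int band) {
  int lookup[256];
  for (int i = 0; i < 256; ++i) lookup[i] = -1;
  for (int i = 0; i < (int)alphabet.size(); ++i) {
    lookup[(unsigned char)alphabet[i]] = i;
    lookup[(unsigned char)std::tolower(alphabet[i])] = i;
  }
  const int n = x.size(), m = y.size();
  std::vector<int> xc(n), yc(m);
  for (int i = 0; i < n; ++i) {
    int c = lookup[(unsigned char)x[i]];
    if (c < 0)
      stop("invalid symbol '%s' at position %d of x",
           std::string(1, x[i]).c_str(), i + 1);
    xc[i] = c;
  }
  for (int j = 0; j < m; ++j) {
    int c = lookup[(unsigned char)y[j]];
    if (c < 0)
      stop("invalid symbol '%s' at position %d of y",
           std::string(1, y[j]).c_str(), j + 1);
    yc[j] = c;
  }
  std::vector<int> gx(n), gy(m);
  for (int i = 0; i < n; ++i) gx[i] = cost(xc[i], gapIndex);
  for (int j = 0; j < m; ++j) gy[j] = cost(yc[j], gapIndex);

  const int diff = n > m ? n - m : m - n;
  const long long wband = band > 0 ? (long long)band + diff : -1;
  // traceback: 0 none, 1 diag, 2 up (consume x), 3 left (consume y)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> prev(m + 1), cur(m + 1);

  prev[0] = 0;
  for (int j = 1; j <= m; ++j) {
    bool ok = band <= 0 || (long long)j <= wband;
    prev[j] = ok && prev[j - 1] < BIG ? prev[j - 1] + gy[j - 1] : BIG;
    if (prev[j] < BIG) tb[j] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1);
    bool ok0 = band <= 0 || (long long)i <= wband;
    cur[0] = ok0 && prev[0] < BIG ? prev[0] + gx[i - 1] : BIG;
    if (cur[0] < BIG) tb[row] = 2;
    for (int j = 1; j <= m; ++j) {
      if (band > 0 && std::llabs((long long)i - j) > wband) {
        cur[j] = BIG;
        continue;
      }
      int best = BIG;
      unsigned char dir = 0;
      if (prev[j - 1] < BIG) {
        best = prev[j - 1] + cost(xc[i - 1], yc[j - 1]);
        dir = 1;
      }
      if (prev[j] < BIG && prev[j] + gx[i - 1] < best) {
        best = prev[j] + gx[i - 1];
        dir = 2;
      }
      if (cur[j - 1] < BIG && cur[j - 1] + gy[j - 1] < best) {
        best = cur[j - 1] + gy[j - 1];
        dir = 3;
      }
      cur[j] = best;
      tb[row + j] = dir;
    }
    std::swap(prev, cur);
  }
  const int total = prev[m];
  if (total >= BIG) stop("alignment band too narrow: no path");

  std::string xg, yg, ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char d = tb[(size_t)i * (m + 1) + j];
    if (d == 1) {
      xg.push_back(x[i - 1]);
      yg.push_back(y[j - 1]);
      ops.push_back('M');
      --i; --j;
    } else if (d == 2) {
      xg.push_back(x[i - 1]);
      yg.push_back(alphabet[gapIndex]);
      ops.push_back('D');
      --i;
    } else if (d == 3) {
      xg.push_back(alphabet[gapIndex]);
      yg.push_back(y[j - 1]);
      ops.push_back('I');
      --j;
    } else {
      stop("internal error: broken traceback");
    }
  }
  std::reverse(xg.begin(), xg.end());
  std::reverse(yg.begin(), yg.end());
  std::reverse(ops.begin(), ops.end());
  return List::create(_["cost"] = total, _["ops"] = ops,
                      _["xGapped"] = xg, _["yGapped"] = yg);
}
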