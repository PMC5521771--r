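// Topographic persistence of local minima on a periodic 2-D grid, by a
// union-find sweep over cells in ascending energy order. The persistence of
// a minimum is the merge level (lowest saddle to a deeper basin) minus its
// own energy; the global minimum gets +Inf.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector grid_persistence(NumericMatrix grid, IntegerVector mins_idx) {
  const int np = grid.nrow(), nq = grid.ncol();
  const int n = np * nq;
  const double *g = grid.begin();

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return g[a] < g[b]; });
  std::vector<int> rank_of(n);
  for (int r = 0; r < n; ++r) rank_of[ord[r]] = r;

  std::vector<int> parent(n), comp_min(n, -1);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };

  std::vector<bool> is_min(n, false);
  std::vector<double> pers(n, NA_REAL);
  for (int k = 0; k < mins_idx.size(); ++k) is_min[mins_idx[k] - 1] = true;

  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int r = 0; r < n; ++r) {
    int cell = ord[r];
    int i = cell % np, j = cell / np;
    comp_min[cell] = cell;
    for (int k = 0; k < 8; ++k) {
      int ii = (i + di[k] + np) % np;
      int jj = (j + dj[k] + nq) % nq;
      int nb = ii + np * jj;
      if (rank_of[nb] < r) {
        int ra = find(cell), rb = find(nb);
        if (ra != rb) {
          int ma = comp_min[ra], mb = comp_min[rb];
          int deeper = (g[ma] <= g[mb]) ? ma : mb;
          int shallower = (g[ma] <= g[mb]) ? mb : ma;
          if (is_min[shallower] && ISNA(pers[shallower]))
            pers[shallower] = g[cell] - g[shallower];
          parent[ra] = rb;
          comp_min[find(rb)] = deeper;
        }
      }
    }
  }

  double gmin = g[ord[0]];
  NumericVector out(mins_idx.size());
  for (int k = 0; k < mins_idx.size(); ++k) {
    int cell = mins_idx[k] - 1;
    double p = pers[cell];
    if (g[cell] == gmin || ISNA(p)) p = R_PosInf;
    out[k] = p;
  }
  return out;
}
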