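// Seeded compact watershed by priority flooding.
//
// Flooding priority of a candidate pixel p claimed by the region grown
// from seed s is  energy(p, s) = gradient(p) + compactness * d(p, seed
// centroid of s)^2  (squared Euclidean pixel distance).  Ties are broken
// by insertion order (FIFO), which makes the labeling deterministic.
// Four-connected neighbourhood; flooding is confined to the mask.

#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  double pri;
  long order;
  int idx;
  int lab;
};

struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.pri != b.pri) return a.pri > b.pri;
    return a.order > b.order;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix compact_watershed_cpp(NumericMatrix grad, IntegerMatrix seeds,
                                    LogicalMatrix mask, double compactness,
                                    NumericVector seedRow,
                                    NumericVector seedCol) {
  const int nr = grad.nrow(), nc = grad.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  long counter = 0;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) lab(i, j) = seeds(i, j);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int l = lab(i, j);
      if (l == 0) continue;
      for (int k = 0; k < 4; ++k) {
        const int ni = i + di[k], nj = j + dj[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (!mask(ni, nj) || lab(ni, nj)) continue;
        const double dr = (ni + 1) - seedRow[l - 1];
        const double dc = (nj + 1) - seedCol[l - 1];
        pq.push({grad(ni, nj) + compactness * (dr * dr + dc * dc), counter++,
                 ni + nj * nr, l});
      }
    }
  }

  while (!pq.empty()) {
    const Node n = pq.top();
    pq.pop();
    const int i = n.idx % nr, j = n.idx / nr;
    if (lab(i, j)) continue;
    lab(i, j) = n.lab;
    for (int k = 0; k < 4; ++k) {
      const int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj)) continue;
      const double dr = (ni + 1) - seedRow[n.lab - 1];
      const double dc = (nj + 1) - seedCol[n.lab - 1];
      pq.push({grad(ni, nj) + compactness * (dr * dr + dc * dc), counter++,
               ni + nj * nr, n.lab});
    }
  }
  return lab;
}
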