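#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a logical matrix.
// Components are numbered 1..n in row-major discovery order (row by row,
// left to right), which fixes fiber_id assignment deterministically.
// connectivity: 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nnb; ++k) {
          int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (mask(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// Multi-source geodesic label propagation: seeds (label > 0) grow into
// `domain` pixels (8-connectivity, chessboard metric), wave by wave so every
// domain pixel receives the label of the geodesically nearest seed.
// Equal-distance ties resolve to the smallest label, deterministically.
// Domain pixels no wave ever reaches keep label 0 (unassigned).
// [[Rcpp::export(name = ".geodesic_label")]]
IntegerMatrix geodesic_label(const IntegerMatrix& seeds, const LogicalMatrix& domain) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  IntegerMatrix lab = clone(seeds);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> frontier;
  frontier.reserve(nr * nc / 4);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) frontier.push_back(j * nr + i);

  std::vector<int> cand_idx;
  while (!frontier.empty()) {
    // collect candidate assignments for this wave, min label wins per pixel
    cand_idx.clear();
    for (size_t t = 0; t < frontier.size(); ++t) {
      int i = frontier[t] % nr, j = frontier[t] / nr;
      int l = lab(i, j);
      for (int k = 0; k < 8; ++k) {
        int r = i + dr[k], c = j + dc[k];
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        if (!domain(r, c)) continue;
        int& cur = lab(r, c);
        if (cur == 0) {
          cur = -l;  // negative = tentative this wave
          cand_idx.push_back(c * nr + r);
        } else if (cur < 0 && -l > cur) {
          cur = -l;  // smaller label replaces
        }
      }
    }
    frontier.clear();
    for (size_t t = 0; t < cand_idx.size(); ++t) {
      int i = cand_idx[t] % nr, j = cand_idx[t] / nr;
      if (lab(i, j) < 0) {
        lab(i, j) = -lab(i, j);
        frontier.push_back(cand_idx[t]);
      }
    }
  }
  // wipe seed labels outside seeds/domain? seeds already labelled; done
  return lab;
}
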