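// Compiled kernels for the segmentation chain: 8-connected component
// labelling and Meyer-style marker-controlled watershed flooding.
#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8-connected component labelling of a binary matrix; labels 1..K in
// row-major order of first encounter, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cc_label8(const IntegerMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + DR[k], nj = cj + DC[k];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct QItem {
  double value;
  long order;
  int idx;
};
struct QCmp {
  // lowest surface value first; FIFO among ties for determinism
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order;
  }
};

// Marker-controlled watershed: floods `surface` (ascending) from the
// labelled `markers`, restricted to `mask`. Pixels reached by two or more
// basins become watershed lines (label 0 on output, like the boundary
// convention of the classic Meyer algorithm). 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix watershed_flood(const NumericMatrix &surface,
                              const IntegerMatrix &markers,
                              const IntegerMatrix &mask) {
  const int nr = surface.nrow(), nc = surface.ncol();
  const int BOUNDARY = -1;
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      lab(i, j) = markers(i, j);

  // seed the queue with unlabelled masked neighbours of every marker pixel
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int ni = i + DR[k], nj = j + DC[k];
        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
        if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
          pq.push({surface(ni, nj), order++, ni + nj * nr});
        }
      }
    }
  }

  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int ci = it.idx % nr, cj = it.idx / nr;
    if (lab(ci, cj) != 0) continue; // already claimed (duplicates allowed)
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int ni = ci + DR[k], nj = cj + DC[k];
      if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
      int l = lab(ni, nj);
      if (l > 0) {
        if (found == 0) {
          found = l;
        } else if (l != found) {
          conflict = true;
          break;
        }
      }
    }
    if (found == 0) continue; // orphaned entry; neighbours became boundary
    if (conflict) {
      lab(ci, cj) = BOUNDARY;
      continue;
    }
    lab(ci, cj) = found;
    for (int k = 0; k < 8; ++k) {
      int ni = ci + DR[k], nj = cj + DC[k];
      if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
      if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
        pq.push({surface(ni, nj), order++, ni + nj * nr});
      }
    }
  }

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) == BOUNDARY) lab(i, j) = 0;
  return lab;
}
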