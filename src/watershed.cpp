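#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8-connected labelling of a boolean mask, deterministic raster-order ids.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + DR8[k], nj = cj + DC8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Regional-maximum plateaus of `dist` within `mask`: 8-connected components
// of equal value with no in-mask neighbour of strictly greater value.
// Each plateau is collapsed to one seed label; labels follow raster order.
// [[Rcpp::export]]
IntegerMatrix regional_max_seeds_cpp(const NumericMatrix dist,
                                     const LogicalMatrix mask) {
  const int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix plat(nr, nc);
  int nplat = 0;
  std::vector<int> stack, members;
  std::vector<bool> is_max;

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || plat(i, j) != 0) continue;
      double v = dist(i, j);
      ++nplat;
      bool ok = true;
      members.clear();
      stack.push_back(i + j * nr);
      plat(i, j) = nplat;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        members.push_back(idx);
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + DR8[k], nj = cj + DC8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (!mask(ni, nj)) continue;
          double w = dist(ni, nj);
          if (w > v) ok = false;
          if (w == v && plat(ni, nj) == 0) {
            plat(ni, nj) = nplat;
            stack.push_back(ni + nj * nr);
          }
        }
      }
      is_max.push_back(ok);
      if (!ok)
        for (int idx : members) plat(idx % nr, idx / nr) = -1;  // not a seed
    }
  }

  // compact surviving plateau ids to 1..K in first-appearance (raster) order
  IntegerMatrix seeds(nr, nc);
  std::vector<int> remap(nplat + 1, 0);
  int next = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int p = plat(i, j);
      if (p > 0) {
        if (remap[p] == 0) remap[p] = ++next;
        seeds(i, j) = remap[p];
      }
    }
  return seeds;
}

struct QEntry {
  double prio;
  long long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // larger distance first
    return a.order > b.order;                      // then first-come
  }
};

// Meyer priority-flood of the (negated) distance map restricted to the mask:
// seeds grow outward from high distance to low; a pixel takes the label that
// first claims it (deterministic given raster push order).
// [[Rcpp::export]]
IntegerMatrix meyer_flood_cpp(const NumericMatrix dist,
                              const LogicalMatrix mask,
                              const IntegerMatrix seeds) {
  const int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long long order = 0;

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) lab(i, j) = seeds(i, j);

  auto push_nbrs = [&](int ci, int cj, int label) {
    for (int k = 0; k < 8; ++k) {
      int ni = ci + DR8[k], nj = cj + DC8[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      pq.push(QEntry{dist(ni, nj), order++, ni + nj * nr, label});
    }
  };

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (lab(i, j) > 0) push_nbrs(i, j, lab(i, j));

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int ci = e.idx % nr, cj = e.idx / nr;
    if (lab(ci, cj) != 0) continue;
    lab(ci, cj) = e.label;
    push_nbrs(ci, cj, e.label);
  }
  return lab;
}
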