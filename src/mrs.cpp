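#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <random>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Multiresolution region-merging segmentation (bottom-up, local mutual
// best fitting). Segments start as single pixels; a pair merges only when
// each is the other's cheapest neighbour and the heterogeneity increase is
// below scale^2. Colour heterogeneity is the size-weighted increase of the
// per-band population SD; shape heterogeneity mixes compactness
// (perimeter / sqrt(n)) and smoothness (perimeter / bounding-box
// perimeter), each size-weighted. 4-connectivity throughout.

struct Seg {
  int n = 0;
  double perim = 0;
  int minr = 0, maxr = 0, minc = 0, maxc = 0;
  std::vector<double> sum, sumsq;
  std::unordered_map<int, int> nb;  // neighbour id -> shared edge length
  bool alive = false;
};

static inline double h_colour(const Seg &s, const std::vector<double> &w) {
  double h = 0;
  for (size_t b = 0; b < w.size(); ++b) {
    double mean = s.sum[b] / s.n;
    double var = s.sumsq[b] / s.n - mean * mean;
    if (var < 0) var = 0;
    h += w[b] * s.n * std::sqrt(var);
  }
  return h;
}

static inline double bbox_perim(int minr, int maxr, int minc, int maxc) {
  return 2.0 * ((maxr - minr + 1) + (maxc - minc + 1));
}

// heterogeneity increase if a and b merge (shared = shared edge length)
static double merge_cost_segs(const Seg &a, const Seg &b, int shared,
                              const std::vector<double> &w, double wshape,
                              double wcmpct) {
  const int nm = a.n + b.n;
  const double pm = a.perim + b.perim - 2.0 * shared;
  double dcol = 0;
  for (size_t bb = 0; bb < w.size(); ++bb) {
    double sum = a.sum[bb] + b.sum[bb];
    double sq = a.sumsq[bb] + b.sumsq[bb];
    double mean = sum / nm;
    double var = sq / nm - mean * mean;
    if (var < 0) var = 0;
    dcol += w[bb] * nm * std::sqrt(var);
  }
  dcol -= h_colour(a, w) + h_colour(b, w);
  const int minr = std::min(a.minr, b.minr), maxr = std::max(a.maxr, b.maxr);
  const int minc = std::min(a.minc, b.minc), maxc = std::max(a.maxc, b.maxc);
  const double d_cmp = pm * std::sqrt((double)nm) -
      (a.perim * std::sqrt((double)a.n) + b.perim * std::sqrt((double)b.n));
  const double d_smo = nm * pm / bbox_perim(minr, maxr, minc, maxc) -
      (a.n * a.perim / bbox_perim(a.minr, a.maxr, a.minc, a.maxc) +
       b.n * b.perim / bbox_perim(b.minr, b.maxr, b.minc, b.maxc));
  const double dshape = wcmpct * d_cmp + (1.0 - wcmpct) * d_smo;
  return (1.0 - wshape) * dcol + wshape * dshape;
}

// exported so the R reference implementation can be cross-checked
// [[Rcpp::export]]
double mrs_pair_cost_cpp(NumericVector na_nb, NumericMatrix sums,
                         NumericMatrix sumsqs, NumericVector perims,
                         IntegerMatrix bboxes, int shared,
                         NumericVector band_w, double wshape, double wcmpct) {
  std::vector<double> w(band_w.begin(), band_w.end());
  Seg a, b;
  a.n = (int)na_nb[0]; b.n = (int)na_nb[1];
  a.perim = perims[0]; b.perim = perims[1];
  a.minr = bboxes(0, 0); a.maxr = bboxes(0, 1);
  a.minc = bboxes(0, 2); a.maxc = bboxes(0, 3);
  b.minr = bboxes(1, 0); b.maxr = bboxes(1, 1);
  b.minc = bboxes(1, 2); b.maxc = bboxes(1, 3);
  for (int k = 0; k < sums.ncol(); ++k) {
    a.sum.push_back(sums(0, k)); b.sum.push_back(sums(1, k));
    a.sumsq.push_back(sumsqs(0, k)); b.sumsq.push_back(sumsqs(1, k));
  }
  return merge_cost_segs(a, b, shared, w, wshape, wcmpct);
}

// [[Rcpp::export]]
IntegerMatrix mrs_segment_cpp(NumericVector values, int nr, int nc, int nbands,
                              NumericVector band_w, double scale,
                              double wshape, double wcmpct, int seed,
                              int max_sweeps) {
  const double thr = scale * scale;
  std::vector<double> w(band_w.begin(), band_w.end());
  const int npix = nr * nc;
  std::vector<Seg> segs(npix);
  std::vector<int> parent(npix);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int id = r + c * nr;  // column-major like R
      Seg &s = segs[id];
      s.n = 1; s.perim = 4;
      s.minr = s.maxr = r; s.minc = s.maxc = c;
      s.sum.resize(nbands); s.sumsq.resize(nbands);
      for (int b = 0; b < nbands; ++b) {
        double v = values[id + (size_t)b * npix];
        s.sum[b] = v; s.sumsq[b] = v * v;
      }
      if (r > 0) { s.nb[id - 1] = 1; }
      if (r < nr - 1) { s.nb[id + 1] = 1; }
      if (c > 0) { s.nb[id - nr] = 1; }
      if (c < nc - 1) { s.nb[id + nr] = 1; }
      s.alive = true;
      parent[id] = id;
    }
  }

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(npix);
  for (int i = 0; i < npix; ++i) order[i] = i;

  auto best_neighbour = [&](int a, double &bestCost) -> int {
    int best = -1;
    bestCost = R_PosInf;
    for (auto &kv : segs[a].nb) {
      double cst = merge_cost_segs(segs[a], segs[kv.first], kv.second,
                                   w, wshape, wcmpct);
      if (cst < bestCost || (cst == bestCost && kv.first < best)) {
        bestCost = cst;
        best = kv.first;
      }
    }
    return best;
  };

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    std::shuffle(order.begin(), order.end(), rng);
    int merges = 0;
    for (int oi = 0; oi < npix; ++oi) {
      const int a = order[oi];
      if (!segs[a].alive || segs[a].nb.empty()) continue;
      double ca;
      int b = best_neighbour(a, ca);
      if (b < 0 || ca >= thr) continue;
      double cb;
      int bb = best_neighbour(b, cb);
      if (bb != a) continue;  // not mutually best fitting
      // merge b into a
      Seg &A = segs[a];
      Seg &B = segs[b];
      const int shared = A.nb[b];
      A.perim = A.perim + B.perim - 2.0 * shared;
      A.n += B.n;
      for (int k = 0; k < nbands; ++k) {
        A.sum[k] += B.sum[k];
        A.sumsq[k] += B.sumsq[k];
      }
      A.minr = std::min(A.minr, B.minr); A.maxr = std::max(A.maxr, B.maxr);
      A.minc = std::min(A.minc, B.minc); A.maxc = std::max(A.maxc, B.maxc);
      A.nb.erase(b);
      for (auto &kv : B.nb) {
        if (kv.first == a) continue;
        A.nb[kv.first] += kv.second;
        Seg &N = segs[kv.first];
        N.nb.erase(b);
        N.nb[a] += kv.second;
      }
      B.alive = false;
      B.nb.clear();
      std::vector<double>().swap(B.sum);
      std::vector<double>().swap(B.sumsq);
      parent[b] = a;
      ++merges;
    }
    if (merges == 0) break;
  }

  // resolve parents (path compression) and relabel contiguously
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  IntegerMatrix labels(nr, nc);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int root = find(r + c * nr);
      auto it = relabel.find(root);
      int lab;
      if (it == relabel.end()) { lab = ++next; relabel[root] = lab; }
      else lab = it->second;
      labels(r, c) = lab;
    }
  }
  return labels;
}
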