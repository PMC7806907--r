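#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sliding-kernel GLCM texture maps.
//
// levels: integer matrix of grey levels in [0, n_levels); k: odd kernel
// size; offsets: n_off x 2 (drow, dcol); symmetric: count both (i,j) and
// (j,i). For each pixel whose centred k x k window lies fully inside the
// image, the co-occurrence histogram over all offsets is normalised and the
// five Haralick-style statistics are evaluated:
//   ASM = sum p^2, Contrast = sum p (i-j)^2, Dissimilarity = sum p |i-j|,
//   Entropy = -sum p log p (natural log, 0 log 0 := 0),
//   Homogeneity = sum p / (1 + (i-j)^2).
// Margin pixels are NA. Counts are maintained sparsely (touched-cell list)
// so small kernels do not pay for the full n_levels^2 table.
// [[Rcpp::export]]
List glcm_texture_maps_cpp(IntegerMatrix levels, int k, int n_levels,
                           IntegerMatrix offsets, bool symmetric) {
  const int nr = levels.nrow(), nc = levels.ncol();
  const int h = (k - 1) / 2;
  const int n_off = offsets.nrow();
  NumericMatrix m_asm(nr, nc), m_con(nr, nc), m_dis(nr, nc),
      m_ent(nr, nc), m_hom(nr, nc);
  std::fill(m_asm.begin(), m_asm.end(), NA_REAL);
  std::fill(m_con.begin(), m_con.end(), NA_REAL);
  std::fill(m_dis.begin(), m_dis.end(), NA_REAL);
  std::fill(m_ent.begin(), m_ent.end(), NA_REAL);
  std::fill(m_hom.begin(), m_hom.end(), NA_REAL);
  if (nr < k || nc < k) return List::create(
      _["asm"] = m_asm, _["contrast"] = m_con, _["dissimilarity"] = m_dis,
      _["entropy"] = m_ent, _["homogeneity"] = m_hom);

  std::vector<double> counts((size_t)n_levels * n_levels, 0.0);
  std::vector<int> touched;
  touched.reserve(4096);

  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      double total = 0.0;
      // enumerate co-occurring pairs inside the window for every offset
      for (int o = 0; o < n_off; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        const int rlo = r - h, rhi = r + h, clo = c - h, chi = c + h;
        const int rA = std::max(rlo, rlo - dr), rB = std::min(rhi, rhi - dr);
        const int cA = std::max(clo, clo - dc), cB = std::min(chi, chi - dc);
        for (int i = rA; i <= rB; ++i) {
          for (int j = cA; j <= cB; ++j) {
            const int a = levels(i, j), b = levels(i + dr, j + dc);
            int idx = a * n_levels + b;
            if (counts[idx] == 0.0) touched.push_back(idx);
            counts[idx] += 1.0;
            total += 1.0;
            if (symmetric) {
              idx = b * n_levels + a;
              if (counts[idx] == 0.0) touched.push_back(idx);
              counts[idx] += 1.0;
              total += 1.0;
            }
          }
        }
      }
      double s_asm = 0, s_con = 0, s_dis = 0, s_ent = 0, s_hom = 0;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int idx = touched[t];
        const double p = counts[idx] / total;
        if (p <= 0) continue;
        const int i = idx / n_levels, j = idx % n_levels;
        const double d = (double)(i - j);
        s_asm += p * p;
        s_con += p * d * d;
        s_dis += p * std::fabs(d);
        s_ent -= p * std::log(p);
        s_hom += p / (1.0 + d * d);
        counts[idx] = 0.0;
      }
      touched.clear();
      m_asm(r, c) = s_asm; m_con(r, c) = s_con; m_dis(r, c) = s_dis;
      m_ent(r, c) = s_ent; m_hom(r, c) = s_hom;
    }
  }
  return List::create(
      _["asm"] = m_asm, _["contrast"] = m_con, _["dissimilarity"] = m_dis,
      _["entropy"] = m_ent, _["homogeneity"] = m_hom);
}
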