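#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap (Gotoh) pairwise alignment over integer-coded sequences.
// a, b: 1-based indices into the substitution matrix `sub`.
// Gap of length L costs gap_open + L * gap_extend (first gap position
// charges gap_open + gap_extend, each further position gap_extend).
// dollar: 1-based code of the neutral pad letter, or 0. Substitution
// scores involving it are taken from `sub` (zero there by
// construction), and a gap that consumes it costs nothing, so any
// alignment column involving the pad scores exactly 0.
// endweight = false leaves leading and trailing gaps unpenalised
// (EMBOSS Needle's default), though they still appear in the reported
// alignment strings.

static const double NEG = -1e30;

// traceback byte layout: bits 0-1 predecessor state of M (0=M,1=X,2=Y),
// bits 2-3 of X, bits 4-5 of Y.
static inline int tb_get(uint8_t v, int state) { return (v >> (2 * state)) & 3; }

// [[Rcpp::export]]
List cpp_nw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend, bool endweight,
                  int dollar) {
  const int na = a.size(), nb = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;

  std::vector<uint8_t> tb((size_t)(na + 1) * (nb + 1), 0);
  std::vector<double> Mp(nb + 1), Xp(nb + 1), Yp(nb + 1);
  std::vector<double> Mc(nb + 1), Xc(nb + 1), Yc(nb + 1);
  // last-column tracker for ends-free mode
  double best_edge = NEG; int best_i = na, best_j = nb, best_state = 0;

  // open/extend cost of a gap consuming letter code c
  auto goc = [&](int c) { return c == dollar ? 0.0 : go; };
  auto gec = [&](int c) { return c == dollar ? 0.0 : ge; };

  // row 0
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= nb; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    if (endweight) {
      Yp[j] = (j == 1 ? -goc(b[0]) : Yp[j - 1] - gec(b[j - 1]));
    } else {
      Yp[j] = 0.0;
    }
    tb[j] = (uint8_t)(2 << 4);  // Y from Y
  }
  for (int i = 1; i <= na; ++i) {
    size_t row = (size_t)i * (nb + 1);
    Mc[0] = NEG; Yc[0] = NEG;
    if (endweight) {
      Xc[0] = (i == 1 ? -goc(a[0]) : Xp[0] - gec(a[i - 1]));
    } else {
      Xc[0] = 0.0;
    }
    tb[row] = (uint8_t)(1 << 2);  // X from X
    for (int j = 1; j <= nb; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M: diagonal from best of three
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      int pm = 0; double dbest = dM;
      if (dX > dbest) { dbest = dX; pm = 1; }
      if (dY > dbest) { dbest = dY; pm = 2; }
      Mc[j] = dbest + s;
      // X: gap in b, consuming a[i-1]
      double oM = Mp[j] - goc(a[i - 1]);
      double oY = Yp[j] - goc(a[i - 1]);
      double eX = Xp[j] - gec(a[i - 1]);
      int px = 1; double xbest = eX;
      if (oM >= xbest) { xbest = oM; px = 0; }
      if (oY > xbest)  { xbest = oY; px = 2; }
      Xc[j] = xbest;
      // Y: gap in a, consuming b[j-1]
      double oM2 = Mc[j - 1] - goc(b[j - 1]);
      double oX2 = Xc[j - 1] - goc(b[j - 1]);
      double eY  = Yc[j - 1] - gec(b[j - 1]);
      int py = 2; double ybest = eY;
      if (oM2 >= ybest) { ybest = oM2; py = 0; }
      if (oX2 > ybest)  { ybest = oX2; py = 1; }
      Yc[j] = ybest;
      tb[row + j] = (uint8_t)(pm | (px << 2) | (py << 4));
      if (!endweight && (j == nb || i == na)) {
        double cb = Mc[j]; int cs = 0;
        if (Xc[j] > cb) { cb = Xc[j]; cs = 1; }
        if (Yc[j] > cb) { cb = Yc[j]; cs = 2; }
        if (cb > best_edge) { best_edge = cb; best_i = i; best_j = j; best_state = cs; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score; int ti, tj, state;
  if (endweight || na == 0 || nb == 0) {
    double cb = Mp[nb]; int cs = 0;
    if (Xp[nb] > cb) { cb = Xp[nb]; cs = 1; }
    if (Yp[nb] > cb) { cb = Yp[nb]; cs = 2; }
    score = cb; ti = na; tj = nb; state = cs;
  } else {
    score = best_edge; ti = best_i; tj = best_j; state = best_state;
  }

  // traceback; build reversed aligned code vectors (0 = gap)
  std::vector<int> ra, rb;
  ra.reserve(na + nb); rb.reserve(na + nb);
  // trailing end-gap padding down to (ti, tj)
  for (int i = na; i > ti; --i) { ra.push_back(a[i - 1]); rb.push_back(0); }
  for (int j = nb; j > tj; --j) { ra.push_back(0); rb.push_back(b[j - 1]); }
  int i = ti, j = tj;
  while (i > 0 || j > 0) {
    uint8_t v = tb[(size_t)i * (nb + 1) + j];
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = tb_get(v, 0); --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back(0);
      state = tb_get(v, 1); --i;
    } else {
      ra.push_back(0); rb.push_back(b[j - 1]);
      state = tb_get(v, 2); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(ra.begin(), ra.end()),
                      _["b"] = IntegerVector(rb.begin(), rb.end()));
}

// Score-only variant (no traceback, O(nb) memory): used by rotation
// scans where only the optimum matters.
// [[Rcpp::export]]
double cpp_nw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend, bool endweight,
                    int dollar) {
  const int na = a.size(), nb = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  auto goc = [&](int c) { return c == dollar ? 0.0 : go; };
  auto gec = [&](int c) { return c == dollar ? 0.0 : ge; };
  std::vector<double> Mp(nb + 1), Xp(nb + 1), Yp(nb + 1);
  std::vector<double> Mc(nb + 1), Xc(nb + 1), Yc(nb + 1);
  double best_edge = NEG;
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= nb; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = endweight ? (j == 1 ? -goc(b[0]) : Yp[j - 1] - gec(b[j - 1])) : 0.0;
  }
  for (int i = 1; i <= na; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = endweight ? (i == 1 ? -goc(a[0]) : Xp[0] - gec(a[i - 1])) : 0.0;
    for (int j = 1; j <= nb; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      Mc[j] = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1])) + s;
      Xc[j] = std::max(std::max(Mp[j], Yp[j]) - goc(a[i - 1]),
                       Xp[j] - gec(a[i - 1]));
      Yc[j] = std::max(std::max(Mc[j - 1], Xc[j - 1]) - goc(b[j - 1]),
                       Yc[j - 1] - gec(b[j - 1]));
      if (!endweight && (j == nb || i == na)) {
        double cb = std::max(Mc[j], std::max(Xc[j], Yc[j]));
        if (cb > best_edge) best_edge = cb;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (endweight || na == 0 || nb == 0)
    return std::max(Mp[nb], std::max(Xp[nb], Yp[nb]));
  return best_edge;
}

// Smith-Waterman local alignment (affine gaps). Returns the optimal
// local score and the aligned position pairs along its path (1-based
// positions into a and b; 0 marks a gap), used to pick an anchor
// column.
// [[Rcpp::export]]
List cpp_sw_local(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int na = a.size(), nb = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<uint8_t> tb((size_t)(na + 1) * (nb + 1), 0);
  // bit 6 set on M-cells that start a fresh alignment
  std::vector<double> Mp(nb + 1, NEG), Xp(nb + 1, NEG), Yp(nb + 1, NEG);
  std::vector<double> Mc(nb + 1), Xc(nb + 1), Yc(nb + 1);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    size_t row = (size_t)i * (nb + 1);
    Mc[0] = NEG; Xc[0] = NEG; Yc[0] = NEG;
    for (int j = 1; j <= nb; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      int pm = 0; double dbest = dM;
      if (dX > dbest) { dbest = dX; pm = 1; }
      if (dY > dbest) { dbest = dY; pm = 2; }
      bool fresh = dbest < 0.0;
      Mc[j] = (fresh ? 0.0 : dbest) + s;
      double oM = Mp[j] - go, oY = Yp[j] - go, eX = Xp[j] - ge;
      int px = 1; double xbest = eX;
      if (oM >= xbest) { xbest = oM; px = 0; }
      if (oY > xbest)  { xbest = oY; px = 2; }
      Xc[j] = xbest;
      double oM2 = Mc[j - 1] - go, oX2 = Xc[j - 1] - go, eY = Yc[j - 1] - ge;
      int py = 2; double ybest = eY;
      if (oM2 >= ybest) { ybest = oM2; py = 0; }
      if (oX2 > ybest)  { ybest = oX2; py = 1; }
      Yc[j] = ybest;
      tb[row + j] = (uint8_t)(pm | (px << 2) | (py << 4) | (fresh ? 64 : 0));
      if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  std::vector<int> pa, pb;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
      uint8_t v = tb[(size_t)i * (nb + 1) + j];
      if (state == 0) {
        pa.push_back(i); pb.push_back(j);
        bool fresh = (v & 64) != 0;
        state = tb_get(v, 0); --i; --j;
        if (fresh) break;
      } else if (state == 1) {
        pa.push_back(i); pb.push_back(0);
        state = tb_get(v, 1); --i;
      } else {
        pa.push_back(0); pb.push_back(j);
        state = tb_get(v, 2); --j;
      }
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());
  }
  return List::create(_["score"] = best,
                      _["a_pos"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_pos"] = IntegerVector(pb.begin(), pb.end()));
}
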