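#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <cstring>
#include <map>
#include <vector>
using namespace Rcpp;

// Half-up rounding (ties toward +Inf), matching the R-level convention.
static inline int round_hu(double x) {
  return (int)std::floor(x + 0.5);
}

// Nearest-neighbour resampling of a label matrix under a similarity
// transform: x' = s R(theta) (x - c_template) + c_moving + (ty, tx).
// Out-of-bounds samples take background label 0.
// [[Rcpp::export]]
IntegerMatrix sample_moving_cpp(IntegerMatrix moving, int trows, int tcols,
                                double tx, double ty, double theta, double s) {
  int mrows = moving.nrow(), mcols = moving.ncol();
  double cr = (trows - 1) / 2.0, cc = (tcols - 1) / 2.0;
  double mr = (mrows - 1) / 2.0, mc = (mcols - 1) / 2.0;
  double th = theta * M_PI / 180.0;
  double a = s * std::cos(th), b = s * std::sin(th);
  IntegerMatrix out(trows, tcols);
  for (int c = 0; c < tcols; ++c) {
    double dc = c - cc;
    for (int r = 0; r < trows; ++r) {
      double dr = r - cr;
      int ri = round_hu(a * dr - b * dc + mr + ty);
      int ci = round_hu(b * dr + a * dc + mc + tx);
      out(r, c) = (ri >= 0 && ri < mrows && ci >= 0 && ci < mcols)
                      ? moving(ri, ci) : 0;
    }
  }
  return out;
}

// Restricted mutual information from a joint count table held as a flat
// (kx+1) x (ky+1) buffer (row-major in x).
static double rmi_from_counts(const std::vector<double>& cnt, int kx, int ky,
                              double m, double alpha, double logbase) {
  int nx = kx + 1, ny = ky + 1;
  std::vector<double> px(nx, 0.0), py(ny, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double p = cnt[x * ny + y] / m;
      px[x] += p;
      py[y] += p;
    }
  double HX = 0.0, HY = 0.0;
  for (int x = 0; x < nx; ++x) if (px[x] > 0) HX -= px[x] * std::log(px[x]);
  for (int y = 0; y < ny; ++y) if (py[y] > 0) HY -= py[y] * std::log(py[y]);
  double p00 = cnt[0] / m;
  double pa00 = (1 - alpha) * p00 + alpha * (px[0] + py[0] - p00);
  double Ha = 0.0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double p = cnt[x * ny + y] / m;
      if (p <= 0) continue;
      double pa;
      if (x == 0 && y == 0) pa = pa00;
      else if (x == 0 || y == 0) pa = (1 - alpha) * p;
      else pa = p;
      if (pa <= 0) return R_NegInf;
      Ha -= p * std::log(pa);
    }
  return (HX + HY - Ha) / logbase;
}

// Restrict [ra, rb] to the r-range where round_hu(c0 + slope * r) stays
// inside [0, m - 1], i.e. c0 + slope * r in [-0.5, m - 0.5).
static inline void clip_range(double c0, double slope, double m, int& ra,
                              int& rb) {
  if (std::fabs(slope) < 1e-9) {
    if (!(c0 >= -0.5 && c0 < m - 0.5)) { ra = 1; rb = 0; }
    return;
  }
  double r1 = (-0.5 - c0) / slope, r2 = (m - 0.5 - c0) / slope;
  if (slope < 0) std::swap(r1, r2);
  // clamp in double before casting so extreme ratios cannot overflow int
  r1 = std::max(r1, ra - 1.0);
  r2 = std::min(r2, rb + 1.0);
  ra = std::max(ra, (int)std::ceil(r1));
  rb = std::min(rb, (int)std::floor(r2));
}

// General single-transform accumulation: per template column the in-bounds
// r-range is computed once so the hot loop has no bounds checks.
static void accumulate_direct(const std::vector<int>& fx,
                              const std::vector<unsigned char>& mov,
                              int trows, int tcols, int mrows, int mcols,
                              double tx, double ty, double theta, double s,
                              std::vector<double>& cnt) {
  double cr = (trows - 1) / 2.0, cc = (tcols - 1) / 2.0;
  double mr = (mrows - 1) / 2.0, mc = (mcols - 1) / 2.0;
  double th = theta * M_PI / 180.0;
  double a = s * std::cos(th), b = s * std::sin(th);
  for (int c = 0; c < tcols; ++c) {
    double dc = c - cc;
    double r0 = a * (-cr) - b * dc + mr + ty;
    double c0 = b * (-cr) + a * dc + mc + tx;
    const int* fcol = fx.data() + (size_t)c * trows;
    int ra = 0, rb = trows - 1;
    clip_range(r0, a, (double)mrows, ra, rb);
    clip_range(c0, b, (double)mcols, ra, rb);
    if (ra > rb) {                        // column entirely off-slide
      for (int r = 0; r < trows; ++r) cnt[fcol[r]] += 1.0;
      continue;
    }
    // guard the boundaries against floating-point edge effects
    while (ra <= rb) {
      int ri = round_hu(r0 + a * ra), ci = round_hu(c0 + b * ra);
      if (ri >= 0 && ri < mrows && ci >= 0 && ci < mcols) break;
      ++ra;
    }
    while (rb >= ra) {
      int ri = round_hu(r0 + a * rb), ci = round_hu(c0 + b * rb);
      if (ri >= 0 && ri < mrows && ci >= 0 && ci < mcols) break;
      --rb;
    }
    for (int r = 0; r < ra; ++r) cnt[fcol[r]] += 1.0;
    for (int r = ra; r <= rb; ++r) {
      int ri = round_hu(r0 + a * r);
      int ci = round_hu(c0 + b * r);
      cnt[fcol[r] + mov[(size_t)ci * mrows + ri]] += 1.0;
    }
    for (int r = rb + 1; r < trows; ++r) cnt[fcol[r]] += 1.0;
  }
}

// Batch objective: for each row (tx, ty, theta, s) of par, resample the
// moving label image onto the template grid, accumulate the joint label
// histogram against the fixed image and return restricted mutual
// information. Labels are packed into bytes and the fixed labels are
// pre-multiplied by the histogram stride. Rows sharing (theta, s) whose
// translations are whole pixels — the optimizer's grids always are — go
// through a fast path: the rotated base indices into a zero-padded copy of
// the moving image are computed once per group, and every translation is
// then a constant offset into that array (no rounding, no bounds checks).
// [[Rcpp::export]]
NumericVector eval_transforms_cpp(IntegerMatrix fixed, IntegerMatrix moving,
                                  int kx, int ky, NumericMatrix par,
                                  double alpha, double base) {
  int trows = fixed.nrow(), tcols = fixed.ncol();
  int mrows = moving.nrow(), mcols = moving.ncol();
  int n = par.nrow();
  int ny = ky + 1;
  double m = (double)trows * tcols;
  double logbase = std::log(base);
  std::vector<int> fx((size_t)trows * tcols);        // fixed label * stride
  for (size_t j = 0; j < fx.size(); ++j) fx[j] = fixed[j] * ny;
  std::vector<unsigned char> mov((size_t)mrows * mcols);
  for (size_t j = 0; j < mov.size(); ++j) mov[j] = (unsigned char)moving[j];
  NumericVector out(n);
  std::vector<double> cnt((kx + 1) * ny);

  // group batch rows by (theta, s) with integer translations
  std::map<std::pair<double, double>, std::vector<int>> groups;
  std::vector<int> singles;
  for (int i = 0; i < n; ++i) {
    double tx = par(i, 0), ty = par(i, 1);
    if (std::fabs(tx - std::floor(tx + 0.5)) < 1e-9 &&
        std::fabs(ty - std::floor(ty + 0.5)) < 1e-9)
      groups[{par(i, 2), par(i, 3)}].push_back(i);
    else singles.push_back(i);
  }
  bool any_group = false;
  for (auto& g : groups)
    if ((int)g.second.size() >= 4) { any_group = true; break; }

  if (any_group) {
    // padded moving image sized for the batch's translation range
    double max_abs_t = 0, max_s = 1;
    for (auto& g : groups) {
      max_s = std::max(max_s, std::fabs(g.first.second));
      for (int i : g.second) {
        max_abs_t = std::max(max_abs_t, std::fabs(par(i, 0)));
        max_abs_t = std::max(max_abs_t, std::fabs(par(i, 1)));
      }
    }
    double cr = (trows - 1) / 2.0, cc = (tcols - 1) / 2.0;
    double Rt = std::sqrt(cr * cr + cc * cc);
    long pad = (long)std::ceil(max_abs_t + max_s * Rt + 3);
    long prows = mrows + 2 * pad, pcols = mcols + 2 * pad;
    std::vector<unsigned char> movp((size_t)prows * pcols, 0);
    for (int c = 0; c < mcols; ++c)
      std::memcpy(movp.data() + (size_t)(c + pad) * prows + pad,
                  mov.data() + (size_t)c * mrows, mrows);
    std::vector<long> lbase((size_t)trows * tcols);
    for (auto& g : groups) {
      double theta = g.first.first, s = g.first.second;
      const std::vector<int>& rows = g.second;
      if ((int)rows.size() < 4) {
        for (int i : rows) {
          std::fill(cnt.begin(), cnt.end(), 0.0);
          accumulate_direct(fx, mov, trows, tcols, mrows, mcols, par(i, 0),
                            par(i, 1), theta, s, cnt);
          out[i] = rmi_from_counts(cnt, kx, ky, m, alpha, logbase);
        }
        continue;
      }
      double th = theta * M_PI / 180.0;
      double a = s * std::cos(th), b = s * std::sin(th);
      double mr = (mrows - 1) / 2.0, mc = (mcols - 1) / 2.0;
      size_t j = 0;
      for (int c = 0; c < tcols; ++c) {
        double dc = c - cc;
        double r0 = a * (-cr) - b * dc + mr;
        double c0 = b * (-cr) + a * dc + mc;
        for (int r = 0; r < trows; ++r, ++j) {
          long ri = round_hu(r0 + a * r) + pad;
          long ci = round_hu(c0 + b * r) + pad;
          lbase[j] = ci * prows + ri;
        }
      }
      // process translations in tiles: one pass over the template pixels
      // serves up to 16 nearby translations, whose moving-image reads share
      // cache lines
      std::vector<int> ord(rows.begin(), rows.end());
      std::sort(ord.begin(), ord.end(), [&](int u, int v) {
        if (par(u, 0) != par(v, 0)) return par(u, 0) < par(v, 0);
        return par(u, 1) < par(v, 1);
      });
      const int TILE = 16;
      int ncell = (kx + 1) * ny;
      std::vector<double> cnts((size_t)TILE * ncell);
      const unsigned char* mp = movp.data();
      for (size_t t0 = 0; t0 < ord.size(); t0 += TILE) {
        int tn = std::min((size_t)TILE, ord.size() - t0);
        long offs[TILE];
        for (int j = 0; j < tn; ++j) {
          int i = ord[t0 + j];
          offs[j] = (long)par(i, 1) + (long)par(i, 0) * prows;
        }
        std::fill(cnts.begin(), cnts.begin() + (size_t)tn * ncell, 0.0);
        for (size_t p = 0; p < lbase.size(); ++p) {
          long bidx = lbase[p];
          int f = fx[p];
          double* cj = cnts.data() + f;
          for (int j = 0; j < tn; ++j, cj += ncell)
            cj[mp[bidx + offs[j]]] += 1.0;
        }
        for (int j = 0; j < tn; ++j) {
          std::copy(cnts.begin() + (size_t)j * ncell,
                    cnts.begin() + (size_t)(j + 1) * ncell, cnt.begin());
          out[ord[t0 + j]] = rmi_from_counts(cnt, kx, ky, m, alpha, logbase);
        }
      }
    }
  } else {
    for (auto& g : groups) singles.insert(singles.end(), g.second.begin(),
                                          g.second.end());
  }
  for (int i : singles) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    accumulate_direct(fx, mov, trows, tcols, mrows, mcols, par(i, 0),
                      par(i, 1), par(i, 2), par(i, 3), cnt);
    out[i] = rmi_from_counts(cnt, kx, ky, m, alpha, logbase);
  }
  return out;
}
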