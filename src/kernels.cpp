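#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Uniform spatial hash over (x, y) with bin size >= 2 * max radius.
// Bins are addressed by integer (bx, by); cells are bucketed per sweep.
struct Hash {
  double cs, width;
  bool cyclic;
  int nbx, nby;
  std::vector<std::vector<int>> bins;
  Hash(const std::vector<double>& x, const std::vector<double>& y,
       double cell_size, double width_, double max_y, bool cyclic_)
      : cs(cell_size), width(width_), cyclic(cyclic_) {
    nbx = std::max(1, (int)std::ceil(width / cs));
    nby = std::max(1, (int)std::ceil((max_y + cs) / cs) + 1);
    bins.assign((size_t)nbx * nby, {});
    for (int i = 0; i < (int)x.size(); ++i) bins[key(x[i], y[i])].push_back(i);
  }
  int key(double xi, double yi) const {
    int bx = (int)std::floor(xi / cs);
    if (cyclic) bx = ((bx % nbx) + nbx) % nbx;
    else bx = std::min(std::max(bx, 0), nbx - 1);
    int by = (int)std::floor(yi / cs);
    if (by < 0) by = 0;
    if (by >= nby) by = nby - 1;
    return by * nbx + bx;
  }
};

static inline double wrap_dx(double dx, double width, bool cyclic) {
  if (!cyclic) return dx;
  if (dx > 0.5 * width) dx -= width;
  else if (dx < -0.5 * width) dx += width;
  return dx;
}

// Iterative pairwise overlap relaxation ("shoving"): every overlapping pair
// is moved apart along the centre line, half the overlap each, updates
// applied immediately in index order (deterministic). Fully superposed
// cells separate along +x. Cells are kept above the substratum
// (y >= radius) and wrapped (cyclic) or clamped laterally.
// [[Rcpp::export]]
List shove_cpp(NumericVector x_, NumericVector y_, NumericVector r_,
               double width, bool cyclic, double tol, int max_sweeps) {
  int n = x_.size();
  std::vector<double> x(x_.begin(), x_.end());
  std::vector<double> y(y_.begin(), y_.end());
  std::vector<double> r(r_.begin(), r_.end());
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double max_ov = 0.0;
  int sweep = 0;
  if (n > 1) {
    double cs = std::max(2.0 * rmax, 1e-6);
    for (sweep = 1; sweep <= max_sweeps; ++sweep) {
      double ymax = 0.0;
      for (int i = 0; i < n; ++i) ymax = std::max(ymax, y[i]);
      Hash h(x, y, cs, width, ymax, cyclic);
      max_ov = 0.0;
      for (int i = 0; i < n; ++i) {
        int bx0 = (int)std::floor(x[i] / cs);
        int by0 = (int)std::floor(y[i] / cs);
        for (int dbx = -1; dbx <= 1; ++dbx) {
          for (int dby = -1; dby <= 1; ++dby) {
            int bx = bx0 + dbx, by = by0 + dby;
            if (by < 0 || by >= h.nby) continue;
            if (!cyclic && (bx < 0 || bx >= h.nbx)) continue;
            int bxx = ((bx % h.nbx) + h.nbx) % h.nbx;
            const std::vector<int>& bucket = h.bins[(size_t)by * h.nbx + bxx];
            for (int j : bucket) {
              if (j <= i) continue;
              double dx = wrap_dx(x[j] - x[i], width, cyclic);
              double dy = y[j] - y[i];
              double sumr = r[i] + r[j];
              double d2 = dx * dx + dy * dy;
              if (d2 >= sumr * sumr) continue;
              double d = std::sqrt(d2);
              double ov = sumr - d;
              double ux, uy;
              if (d < 1e-9) { ux = 1.0; uy = 0.0; ov = sumr; }
              else { ux = dx / d; uy = dy / d; }
              max_ov = std::max(max_ov, ov / sumr);
              double half = 0.5 * ov;
              x[i] -= ux * half; y[i] -= uy * half;
              x[j] += ux * half; y[j] += uy * half;
              if (y[i] < r[i]) y[i] = r[i];
              if (y[j] < r[j]) y[j] = r[j];
            }
          }
        }
      }
      for (int i = 0; i < n; ++i) {
        if (cyclic) {
          x[i] -= width * std::floor(x[i] / width);
        } else {
          if (x[i] < r[i]) x[i] = r[i];
          if (x[i] > width - r[i]) x[i] = width - r[i];
        }
        if (y[i] < r[i]) y[i] = r[i];
      }
      if (max_ov < tol) break;
    }
    if (sweep > max_sweeps) sweep = max_sweeps;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["sweeps"] = sweep, _["max_overlap"] = max_ov);
}

// Per-cell counts of same-species and total neighbors within `radius`
// (self excluded); lateral wrap optional. Species given as integer codes.
// [[Rcpp::export]]
IntegerMatrix neighbor_counts_cpp(NumericVector x, NumericVector y,
                                  IntegerVector sp, double radius,
                                  double width, bool cyclic) {
  int n = x.size();
  IntegerMatrix out(n, 2);
  if (n == 0) return out;
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double ymax = 0.0;
  for (int i = 0; i < n; ++i) ymax = std::max(ymax, yv[i]);
  double cs = std::max(radius, 1e-6);
  Hash h(xv, yv, cs, width, ymax, cyclic);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int bx0 = (int)std::floor(xv[i] / cs);
    int by0 = (int)std::floor(yv[i] / cs);
    int same = 0, tot = 0;
    for (int dbx = -1; dbx <= 1; ++dbx) {
      for (int dby = -1; dby <= 1; ++dby) {
        int bx = bx0 + dbx, by = by0 + dby;
        if (by < 0 || by >= h.nby) continue;
        if (!cyclic && (bx < 0 || bx >= h.nbx)) continue;
        int bxx = ((bx % h.nbx) + h.nbx) % h.nbx;
        const std::vector<int>& bucket = h.bins[(size_t)by * h.nbx + bxx];
        for (int j : bucket) {
          if (j == i) continue;
          double dx = wrap_dx(xv[j] - xv[i], width, cyclic);
          double dy = yv[j] - yv[i];
          if (dx * dx + dy * dy <= r2) {
            ++tot;
            if (sp[j] == sp[i]) ++same;
          }
        }
      }
    }
    out(i, 0) = same;
    out(i, 1) = tot;
  }
  return out;
}
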