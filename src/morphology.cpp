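#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e20;

// Felzenszwalb & Huttenlocher 1D squared distance transform (lower envelope
// of parabolas). f: sampled function, d: output, n: length, v/z: work arrays.
static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (voxel centres) from every TRUE voxel to
// the nearest FALSE voxel; 0 on FALSE voxels. dim has length 2 or 3,
// column-major layout as in R arrays. If no FALSE voxel exists the result
// exceeds 1e19 everywhere (caller detects).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? DT_INF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along first dimension
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f.data(), d.data(), n1, v.data(), z.data());
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // along second dimension
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f.data(), d.data(), n2, v.data(), z.data());
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // along third dimension
  if (n3 > 1) {
    R_xlen_t plane = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t base = i + (R_xlen_t)n1 * j;
        for (int k = 0; k < n3; k++) f[k] = out[base + plane * k];
        dt1d(f.data(), d.data(), n3, v.data(), z.data());
        for (int k = 0; k < n3; k++) out[base + plane * k] = d[k];
      }
  }
  return out;
}

// Local thickness by inscribed-sphere cover: for every foreground voxel p,
// the maximum r2(c) over foreground centres c whose open sphere of squared
// radius r2(c) contains p (||p-c||^2 < r2(c)). r2 is the exact squared EDT.
// Returns the squared radius field; thickness = 2*sqrt(out)*voxel.
// Centres whose sphere is contained in a 26-neighbour's sphere are skipped
// (exact integer containment test), which leaves the result unchanged.
// [[Rcpp::export]]
NumericVector cpp_local_thickness_sq(LogicalVector mask, IntegerVector dim,
                                     NumericVector r2) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  R_xlen_t n = plane * n3;
  NumericVector out(n);

  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t idx = i + (R_xlen_t)n1 * j + plane * k;
        if (!mask[idx]) continue;
        double rc2 = r2[idx];

        // redundancy check against 26-neighbourhood:
        // contained iff sqrt(r2') >= sqrt(rc2) + d, with d2 = dz^2+dy^2+dx^2
        // <=> a = r2' - rc2 - d2 >= 0 and a^2 >= 4*d2*rc2 (exact in integers)
        bool redundant = false;
        for (int dk = -1; dk <= 1 && !redundant; dk++)
          for (int dj = -1; dj <= 1 && !redundant; dj++)
            for (int di = -1; di <= 1 && !redundant; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
                continue;
              R_xlen_t nidx = ii + (R_xlen_t)n1 * jj + plane * kk;
              if (!mask[nidx]) continue;
              double rn2 = r2[nidx];
              double d2 = (double)(di * di + dj * dj + dk * dk);
              double a = rn2 - rc2 - d2;
              if (a >= 0.0 && a * a >= 4.0 * d2 * rc2) redundant = true;
            }
        if (redundant) continue;

        int R = (int)std::floor(std::sqrt(rc2 - 1.0) + 1e-9);
        if (rc2 <= 1.0) R = 0;
        for (int dk = -R; dk <= R; dk++) {
          int kk = k + dk;
          if (kk < 0 || kk >= n3) continue;
          for (int dj = -R; dj <= R; dj++) {
            int jj = j + dj;
            if (jj < 0 || jj >= n2) continue;
            double dd = (double)(dk * dk + dj * dj);
            if (dd >= rc2) continue;
            R_xlen_t rowbase = (R_xlen_t)n1 * jj + plane * kk;
            for (int di = -R; di <= R; di++) {
              int ii = i + di;
              if (ii < 0 || ii >= n1) continue;
              if (dd + di * di < rc2) {
                R_xlen_t p = ii + rowbase;
                if (out[p] < rc2) out[p] = rc2;
              }
            }
          }
        }
      }
  return out;
}

// Connected-component labelling, conn = 6 (face) or 26 (face+edge+corner);
// on a (n1,n2,1) array these reduce to 4- and 8-connectivity. Components are
// numbered 1..K in first-encounter scan order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int conn) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  R_xlen_t n = plane * n3;
  IntegerVector lab(n);

  std::vector<std::array<int, 3> > offs;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (conn == 6 && m > 1) continue;
        offs.push_back({di, dj, dk});
      }

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / plane);
      int rem = (int)(cur - (R_xlen_t)k * plane);
      int j = rem / n1;
      int i = rem - j * n1;
      for (size_t o = 0; o < offs.size(); o++) {
        int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t q = ii + (R_xlen_t)n1 * jj + plane * kk;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Guo-Hall two-subiteration thinning of a 2D mask (column-major nr x nc).
// Produces a thin, 8-connected, topology-preserving skeleton.
// [[Rcpp::export]]
LogicalVector cpp_thin2d(LogicalVector mask, int nr, int nc) {
  std::vector<unsigned char> img((size_t)nr * nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; i++) img[i] = mask[i] ? 1 : 0;

#define PX(i, j) (((i) < 0 || (i) >= nr || (j) < 0 || (j) >= nc) ? 0 : img[(i) + (size_t)nr * (j)])

  std::vector<R_xlen_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; iter++) {
      kill.clear();
      for (int j = 0; j < nc; j++)
        for (int i = 0; i < nr; i++) {
          if (!img[i + (size_t)nr * j]) continue;
          int p2 = PX(i - 1, j), p3 = PX(i - 1, j + 1), p4 = PX(i, j + 1);
          int p5 = PX(i + 1, j + 1), p6 = PX(i + 1, j), p7 = PX(i + 1, j - 1);
          int p8 = PX(i, j - 1), p9 = PX(i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                              : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back(i + (R_xlen_t)nr * j);
        }
      if (!kill.empty()) changed = true;
      for (size_t s = 0; s < kill.size(); s++) img[kill[s]] = 0;
    }
  }
#undef PX

  LogicalVector out((R_xlen_t)nr * nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; i++) out[i] = img[i] != 0;
  return out;
}

// Separable Gaussian blur with half-sample symmetric (reflecting) boundary.
// sigma in voxels; kernel truncated at ceil(3.5*sigma) and renormalised.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  R_xlen_t n = plane * n3;
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;

  int rad = (int)std::ceil(3.5 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; t++) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (size_t t = 0; t < ker.size(); t++) ker[t] /= s;

  // reflect index into [0, len)
  auto refl = [](int x, int len) {
    if (len == 1) return 0;
    int period = 2 * len;
    x = ((x % period) + period) % period;
    return (x < len) ? x : (period - 1 - x);
  };

  std::vector<double> line(std::max(n1, std::max(n2, n3)));
  NumericVector tmp(n);

  // axis 1
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * j + plane * k;
      for (int i = 0; i < n1; i++) line[i] = out[base + i];
      for (int i = 0; i < n1; i++) {
        double acc = 0;
        for (int t = -rad; t <= rad; t++)
          acc += ker[t + rad] * line[refl(i + t, n1)];
        tmp[base + i] = acc;
      }
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + plane * k;
      for (int j = 0; j < n2; j++) line[j] = tmp[base + (R_xlen_t)n1 * j];
      for (int j = 0; j < n2; j++) {
        double acc = 0;
        for (int t = -rad; t <= rad; t++)
          acc += ker[t + rad] * line[refl(j + t, n2)];
        out[base + (R_xlen_t)n1 * j] = acc;
      }
    }
  // axis 3
  if (n3 > 1) {
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t base = i + (R_xlen_t)n1 * j;
        for (int k = 0; k < n3; k++) line[k] = out[base + plane * k];
        for (int k = 0; k < n3; k++) {
          double acc = 0;
          for (int t = -rad; t <= rad; t++)
            acc += ker[t + rad] * line[refl(k + t, n3)];
          out[base + plane * k] = acc;
        }
      }
  }
  return out;
}
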