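#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Volumes are numeric arrays with dim = c(nz, ny, nx), column-major:
// linear index = z + nz*y + nz*ny*x (0-based).

static inline int reflect(int i, int n) {
  // mirror boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// separable 1D Gaussian pass along one axis (0=z, 1=y, 2=x)
static void gauss_pass(std::vector<double>& v, int nz, int ny, int nx,
                       int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& kv : k) kv /= s;

  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)nz : (long)nz * ny;
  // iterate over all lines along 'axis'
  long nzy = (long)nz * ny;
  std::vector<double> line(n), out(n);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        if (axis == 0 && z > 0) break;
        if (axis == 1 && y > 0) break;
        if (axis == 2 && x > 0) break;
        // base index of this line
        long base;
        int nl1, nl2; // the two perpendicular extents
        (void)nl1; (void)nl2;
        if (axis == 0) base = (long)nz * y + nzy * x;
        else if (axis == 1) base = z + nzy * x;
        else base = z + (long)nz * y;
        for (int i = 0; i < n; ++i) line[i] = v[base + stride * i];
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j)
            acc += k[j + r] * line[reflect(i + j, n)];
          out[i] = acc;
        }
        for (int i = 0; i < n; ++i) v[base + stride * i] = out[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  // loops above only walk the correct perpendicular plane; rewrite cleanly:
  // pass along z for every (y,x); along y for every (z,x); along x for (z,y)
  gauss_pass(v, nz, ny, nx, 0, sigma_vox[0]);
  gauss_pass(v, nz, ny, nx, 1, sigma_vox[1]);
  gauss_pass(v, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector res(v.begin(), v.end());
  res.attr("dim") = dim;
  return res;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing w; f is the input squared distance, d the output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> vtx(n);
  std::vector<double> zb(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // infinite parabolas never form the envelope
    double s = 0.0;
    while (k >= 0) {
      int p = vtx[k];
      s = ((f[q] + w * w * q * q) - (f[p] + w * w * p * p)) /
          (2.0 * w * w * (q - p));
      if (s <= zb[k]) --k; else break;
    }
    ++k;
    vtx[k] = q;
    zb[k] = (k == 0) ? -INF : s;
    zb[k + 1] = INF;
  }
  if (k < 0) {  // no finite source on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    // s and zb are in index units (the parabola intersection formula
    // divides the physical coordinate by w), so compare against q
    while (j < k && zb[j + 1] < (double)q) ++j;
    int p = vtx[j];
    d[q] = w * w * (double)(q - p) * (q - p) + f[p];
  }
}

// Anisotropic squared Euclidean distance (um^2) to the nearest foreground
// (non-zero) voxel. Voxels in the foreground get 0; all-background input
// yields +Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing_zyx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  std::vector<double> d(nvox);
  const double INF = std::numeric_limits<double>::infinity();
  for (long i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : INF;

  long nzy = (long)nz * ny;
  // pass along z
  {
    std::vector<double> f(nz), o(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        long base = (long)nz * y + nzy * x;
        for (int z = 0; z < nz; ++z) f[z] = d[base + z];
        dt1d(f, o, nz, spacing_zyx[0]);
        for (int z = 0; z < nz; ++z) d[base + z] = o[z];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), o(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        long base = z + nzy * x;
        for (int y = 0; y < ny; ++y) f[y] = d[base + (long)nz * y];
        dt1d(f, o, ny, spacing_zyx[1]);
        for (int y = 0; y < ny; ++y) d[base + (long)nz * y] = o[y];
      }
  }
  // pass along x
  {
    std::vector<double> f(nx), o(nx);
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long base = z + (long)nz * y;
        for (int x = 0; x < nx; ++x) f[x] = d[base + nzy * x];
        dt1d(f, o, nx, spacing_zyx[2]);
        for (int x = 0; x < nx; ++x) d[base + nzy * x] = o[x];
      }
  }
  NumericVector res(d.begin(), d.end());
  res.attr("dim") = dim;
  return res;
}

// In-plane (per Z-slice) median filter over a disc of pixel radius r,
// restricted to in-bounds pixels (FIJI convention). r = 0 is identity.
// [[Rcpp::export]]
NumericVector cpp_median_disc(NumericVector vol, IntegerVector dim, int r) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector res = clone(vol);
  if (r <= 0) return res;
  std::vector<int> dy, dx;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if (a * a + b * b <= r * r) { dy.push_back(a); dx.push_back(b); }
  int nk = (int)dy.size();
  long nzy = (long)nz * ny;
  std::vector<double> buf(nk);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int m = 0;
        for (int k = 0; k < nk; ++k) {
          int yy = y + dy[k], xx = x + dx[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          buf[m++] = vol[z + (long)nz * yy + nzy * xx];
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        double med = buf[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
          med = 0.5 * (med + lo);
        }
        res[z + (long)nz * y + nzy * x] = med;
      }
  return res;
}

// Replace voxels exceeding 'factor' times the median of their in-plane
// 3x3 neighbourhood (centre included, in-bounds pixels only) by that median.
// [[Rcpp::export]]
NumericVector cpp_remove_outliers(NumericVector vol, IntegerVector dim,
                                  double factor) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector res = clone(vol);
  long nzy = (long)nz * ny;
  std::vector<double> buf(9);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int m = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            int yy = y + a, xx = x + b;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            buf[m++] = vol[z + (long)nz * yy + nzy * xx];
          }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        double med = buf[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
          med = 0.5 * (med + lo);
        }
        long idx = z + (long)nz * y + nzy * x;
        if (vol[idx] > factor * med) res[idx] = med;
      }
  return res;
}

// Plateau-tolerant local maxima above a threshold within an ellipsoidal
// neighbourhood of voxel radii (rz, ry, rx). Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               NumericVector rad_zyx, double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double rz = std::max(rad_zyx[0], 0.0), ry = std::max(rad_zyx[1], 0.0),
         rx = std::max(rad_zyx[2], 0.0);
  int irz = (int)std::floor(rz), iry = (int)std::floor(ry),
      irx = (int)std::floor(rx);
  std::vector<int> oz, oy, ox;
  for (int a = -irz; a <= irz; ++a)
    for (int b = -iry; b <= iry; ++b)
      for (int c = -irx; c <= irx; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        double q = 0.0;
        if (rz > 0) q += (double)a * a / (rz * rz);
        else if (a != 0) continue;
        if (ry > 0) q += (double)b * b / (ry * ry);
        else if (b != 0) continue;
        if (rx > 0) q += (double)c * c / (rx * rx);
        else if (c != 0) continue;
        if (q <= 1.0) { oz.push_back(a); oy.push_back(b); ox.push_back(c); }
      }
  int nk = (int)oz.size();
  long nzy = (long)nz * ny;
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long idx = z + (long)nz * y + nzy * x;
        double v = vol[idx];
        if (!(v > threshold)) continue;
        bool ok = true;
        for (int k = 0; k < nk; ++k) {
          int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          if (vol[zz + (long)nz * yy + nzy * xx] > v) { ok = false; break; }
        }
        if (ok) hits.push_back((int)(idx + 1));
      }
  return IntegerVector(hits.begin(), hits.end());
}
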