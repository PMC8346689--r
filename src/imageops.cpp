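// Low-level 3D image kernels: resampling, separable Gaussian smoothing,
// smoothed-one-hot label warping, exact squared Euclidean distance transform,
// finite-difference gradients and the demons force. Arrays are column-major
// (x fastest), voxel coordinates are 0-based doubles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample with constant out-of-bounds value.
static double sample_tri(const double* v, int X, int Y, int Z,
                         double x, double y, double z, double oob) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)X || y >= (double)Y || z >= (double)Z)
    return oob;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    int zz = z0 + dz;
    for (int dy = 0; dy < 2; ++dy) {
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      int yy = y0 + dy;
      for (int dx = 0; dx < 2; ++dx) {
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        int xx = x0 + dx;
        double val;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= X || yy >= Y || zz >= Z)
          val = oob;
        else
          val = v[(size_t)xx + (size_t)X * ((size_t)yy + (size_t)Y * zz)];
        acc += wx * wy * wz * val;
      }
    }
  }
  return acc;
}

static double sample_nn(const double* v, int X, int Y, int Z,
                        double x, double y, double z, double oob) {
  int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= X || yi >= Y || zi >= Z) return oob;
  return v[(size_t)xi + (size_t)X * ((size_t)yi + (size_t)Y * zi)];
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           NumericMatrix coords, int order, double oob) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  const double* cx = &coords(0, 0);
  const double* cy = &coords(0, 1);
  const double* cz = &coords(0, 2);
  if (order == 0) {
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = sample_nn(v, X, Y, Z, cx[i], cy[i], cz[i], oob);
  } else {
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = sample_tri(v, X, Y, Z, cx[i], cy[i], cz[i], oob);
  }
  return out;
}

// Separable Gaussian smoothing, zero-padded, kernel truncated at 3 sigma.
static void smooth_axis(std::vector<double>& v, int X, int Y, int Z,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& w : k) w /= s;
  int n[3] = {X, Y, Z};
  size_t stride[3] = {1, (size_t)X, (size_t)X * Y};
  int L = n[axis];
  size_t st = stride[axis];
  // iterate over all lines along `axis`
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> line(L);
  for (int j2 = 0; j2 < n[a2]; ++j2) {
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      size_t base = (size_t)j1 * stride[a1] + (size_t)j2 * stride[a2];
      for (int i = 0; i < L; ++i) line[i] = v[base + (size_t)i * st];
      for (int i = 0; i < L; ++i) {
        double acc = 0;
        int lo = std::max(0, i - r), hi = std::min(L - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += line[j] * k[j - i + r];
        v[base + (size_t)i * st] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma) {
  std::vector<double> v(vol.begin(), vol.end());
  smooth_axis(v, dims[0], dims[1], dims[2], 0, sigma[0]);
  smooth_axis(v, dims[0], dims[1], dims[2], 1, sigma[1]);
  smooth_axis(v, dims[0], dims[1], dims[2], 2, sigma[2]);
  NumericVector out(vol.size());
  std::copy(v.begin(), v.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Smoothed-one-hot label warp: each class indicator is Gaussian-smoothed
// (sigma in voxels of the source grid), trilinearly sampled at `coords`,
// and the voxel takes the argmax class (ties -> lowest code). Label 0 is
// treated as background with value 1 outside the source grid.
// [[Rcpp::export]]
IntegerVector cpp_warp_labels(IntegerVector labels, IntegerVector dims,
                              NumericMatrix coords, double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t nv = (size_t)X * Y * Z;
  const R_xlen_t n = coords.nrow();
  std::vector<int> codes;
  {
    std::set<int> s(labels.begin(), labels.end());
    s.insert(0);
    codes.assign(s.begin(), s.end());
  }
  IntegerVector out(n);
  std::vector<double> best(n, -std::numeric_limits<double>::infinity());
  const double* cx = &coords(0, 0);
  const double* cy = &coords(0, 1);
  const double* cz = &coords(0, 2);
  std::vector<double> ind(nv);
  for (int code : codes) {
    for (size_t i = 0; i < nv; ++i) ind[i] = (labels[i] == code) ? 1.0 : 0.0;
    if (sigma > 0) {
      smooth_axis(ind, X, Y, Z, 0, sigma);
      smooth_axis(ind, X, Y, Z, 1, sigma);
      smooth_axis(ind, X, Y, Z, 2, sigma);
    }
    double oob = (code == 0) ? 1.0 : 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double sc = (sigma > 0)
                      ? sample_tri(ind.data(), X, Y, Z, cx[i], cy[i], cz[i], oob)
                      : sample_nn(ind.data(), X, Y, Z, cx[i], cy[i], cz[i], oob);
      if (sc > best[i]) {
        best[i] = sc;
        out[i] = code;
      }
    }
  }
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform on a sampled grid
// with physical sample spacing `s`.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s, vv;
    while (true) {
      vv = (double)v[k] * s;
      double sep = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (sep <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * s;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
  f = d;
}

// Exact squared Euclidean distance (mm^2) to the nearest nonzero voxel.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t nv = (size_t)X * Y * Z;
  const double INF = 1e30;
  std::vector<double> d(nv);
  for (size_t i = 0; i < nv; ++i) d[i] = mask[i] ? 0.0 : INF;
  int n[3] = {X, Y, Z};
  size_t stride[3] = {1, (size_t)X, (size_t)X * Y};
  for (int axis = 0; axis < 3; ++axis) {
    int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    int L = n[axis];
    size_t st = stride[axis];
    std::vector<double> line(L);
    for (int j2 = 0; j2 < n[a2]; ++j2) {
      for (int j1 = 0; j1 < n[a1]; ++j1) {
        size_t base = (size_t)j1 * stride[a1] + (size_t)j2 * stride[a2];
        for (int i = 0; i < L; ++i) line[i] = d[base + (size_t)i * st];
        dt1d(line, spacing[axis]);
        for (int i = 0; i < L; ++i) d[base + (size_t)i * st] = line[i];
      }
    }
  }
  NumericVector out(nv);
  std::copy(d.begin(), d.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Central-difference gradient (voxel units), one-sided at borders.
// [[Rcpp::export]]
List cpp_gradient3(NumericVector vol, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector gx(vol.size()), gy(vol.size()), gz(vol.size());
  const double* v = vol.begin();
  auto at = [&](int x, int y, int z) {
    return v[(size_t)x + (size_t)X * ((size_t)y + (size_t)Y * z)];
  };
  size_t i = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++i) {
        int xm = clampi(x - 1, 0, X - 1), xp = clampi(x + 1, 0, X - 1);
        int ym = clampi(y - 1, 0, Y - 1), yp = clampi(y + 1, 0, Y - 1);
        int zm = clampi(z - 1, 0, Z - 1), zp = clampi(z + 1, 0, Z - 1);
        gx[i] = (at(xp, y, z) - at(xm, y, z)) / (double)(xp - xm ? xp - xm : 1);
        gy[i] = (at(x, yp, z) - at(x, ym, z)) / (double)(yp - ym ? yp - ym : 1);
        gz[i] = (at(x, y, zp) - at(x, y, zm)) / (double)(zp - zm ? zp - zm : 1);
      }
  gx.attr("dim") = dims;
  gy.attr("dim") = dims;
  gz.attr("dim") = dims;
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}

// Thirion demons force: u = (F - M) grad(M) / (|grad M|^2 + (F - M)^2),
// zeroed where the denominator is tiny. Displacements in voxels.
// [[Rcpp::export]]
List cpp_demons_force(NumericVector fixedv, NumericVector moving_warped,
                      NumericVector gx, NumericVector gy, NumericVector gz) {
  R_xlen_t n = fixedv.size();
  NumericVector ux(n), uy(n), uz(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double diff = fixedv[i] - moving_warped[i];
    double g2 = gx[i] * gx[i] + gy[i] * gy[i] + gz[i] * gz[i];
    double den = g2 + diff * diff;
    if (den < 1e-9) continue;
    double f = diff / den;
    ux[i] = f * gx[i];
    uy[i] = f * gy[i];
    uz[i] = f * gz[i];
  }
  return List::create(_["x"] = ux, _["y"] = uy, _["z"] = uz);
}

// Normalized cross-correlation between two equal-length vectors,
// optionally restricted to a mask.
// [[Rcpp::export]]
double cpp_ncc(NumericVector a, NumericVector b) {
  R_xlen_t n = a.size();
  double ma = 0, mb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    ma += a[i];
    mb += b[i];
  }
  ma /= n;
  mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db;
    saa += da * da;
    sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}
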