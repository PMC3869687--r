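// Compiled kernels for the voxel-level primitives: resampling, connected
// components, separable convolution, binary morphology, EM responsibilities
// and the permutation max-cluster loop. All voxel indices are 0-based here;
// R wrappers own the 0/1-based conversion.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sample_trilinear(const double* src, const int* d,
                                      double x, double y, double z) {
  // corners outside the grid contribute 0 (air / zero probability)
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)d[0] || y >= (double)d[1] || z >= (double)d[2]) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz; if (zz < 0 || zz >= d[2]) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy; if (yy < 0 || yy >= d[1]) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx; if (xx < 0 || xx >= d[0]) continue;
        double wx = dx ? fx : 1.0 - fx;
        out += wx * wy * wz * src[xx + (size_t)d[0] * (yy + (size_t)d[1] * zz)];
      }
    }
  }
  return out;
}

static inline double sample_nearest(const double* src, const int* d,
                                    double x, double y, double z) {
  int xx = (int)std::lround(x), yy = (int)std::lround(y), zz = (int)std::lround(z);
  if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
    return 0.0;
  return src[xx + (size_t)d[0] * (yy + (size_t)d[1] * zz)];
}

// Resample src (dims sdim) onto an output grid (dims odim); M is the 4x4
// matrix taking 0-based output voxel indices to 0-based source voxel coords.
// [[Rcpp::export]]
NumericVector cppResample(NumericVector src, IntegerVector sdim,
                          IntegerVector odim, NumericMatrix M, int nearest) {
  int sd[3] = {sdim[0], sdim[1], sdim[2]};
  size_t nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out(nx * ny * nz);
  const double* s = src.begin();
  double* o = out.begin();
  double m00=M(0,0),m01=M(0,1),m02=M(0,2),m03=M(0,3);
  double m10=M(1,0),m11=M(1,1),m12=M(1,2),m13=M(1,3);
  double m20=M(2,0),m21=M(2,1),m22=M(2,2),m23=M(2,3);
  size_t p = 0;
  for (size_t k = 0; k < nz; ++k)
    for (size_t j = 0; j < ny; ++j) {
      double bx = m01*j + m02*k + m03, by = m11*j + m12*k + m13,
             bz = m21*j + m22*k + m23;
      for (size_t i = 0; i < nx; ++i, ++p) {
        double x = m00*i + bx, y = m10*i + by, z = m20*i + bz;
        o[p] = nearest ? sample_nearest(s, sd, x, y, z)
                       : sample_trilinear(s, sd, x, y, z);
      }
    }
  return out;
}

// Sample src at arbitrary 0-based voxel coordinates (N x 3 matrix).
// [[Rcpp::export]]
NumericVector cppSampleAt(NumericVector src, IntegerVector sdim,
                          NumericMatrix coords, int nearest) {
  int sd[3] = {sdim[0], sdim[1], sdim[2]};
  int n = coords.nrow();
  NumericVector out(n);
  const double* s = src.begin();
  for (int i = 0; i < n; ++i) {
    double x = coords(i,0), y = coords(i,1), z = coords(i,2);
    out[i] = nearest ? sample_nearest(s, sd, x, y, z)
                     : sample_trilinear(s, sd, x, y, z);
  }
  return out;
}

// Partial-volume fractions of an integer label volume sampled at arbitrary
// voxel coordinates: each point distributes its 8 trilinear corner weights
// onto the corners' labels. Out-of-field weight goes to label 0 (air).
// [[Rcpp::export]]
NumericMatrix cppLabelFractions(IntegerVector lab, IntegerVector sdim,
                                NumericMatrix coords, int nlab) {
  int d0 = sdim[0], d1 = sdim[1], d2 = sdim[2];
  int n = coords.nrow();
  NumericMatrix out(n, nlab);
  for (int i = 0; i < n; ++i) {
    double x = coords(i,0), y = coords(i,1), z = coords(i,2);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      int zz = z0 + dz;
      double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        int yy = y0 + dy;
        double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = x0 + dx;
          double w = (dx ? fx : 1.0 - fx) * wy * wz;
          if (w <= 0) continue;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= d0 || yy >= d1 ||
              zz >= d2) continue;
          int lv = lab[xx + (size_t)d0 * (yy + (size_t)d1 * zz)];
          if (lv >= 0 && lv < nlab) { out(i, lv) += w; acc += w; }
        }
      }
    }
    if (acc < 1.0) out(i, 0) += 1.0 - acc;   // outside field = air
  }
  return out;
}

// Mean squared difference between template values tv and the source sampled
// at B %*% [x;1] (B: 3x4 world-to-source-voxel map), after optimal global
// intensity scaling of the source. X: N x 3 template-space world points.
// [[Rcpp::export]]
double cppScaledMseAt(NumericVector src, IntegerVector sdim, NumericMatrix X,
                      NumericVector tv, NumericMatrix B) {
  int sd[3] = {sdim[0], sdim[1], sdim[2]};
  int n = X.nrow();
  const double* s = src.begin();
  std::vector<double> sv((size_t)n);
  double b00=B(0,0),b01=B(0,1),b02=B(0,2),b03=B(0,3);
  double b10=B(1,0),b11=B(1,1),b12=B(1,2),b13=B(1,3);
  double b20=B(2,0),b21=B(2,1),b22=B(2,2),b23=B(2,3);
  double ss = 0.0, st = 0.0;
  for (int i = 0; i < n; ++i) {
    double wx = X(i,0), wy = X(i,1), wz = X(i,2);
    double v = sample_trilinear(s, sd,
                                b00*wx + b01*wy + b02*wz + b03,
                                b10*wx + b11*wy + b12*wz + b13,
                                b20*wx + b21*wy + b22*wz + b23);
    sv[i] = v;
    ss += v * v;
    st += v * tv[i];
  }
  double a = (ss > 1e-12) ? st / ss : 0.0;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = tv[i] - a * sv[i];
    acc += r * r;
  }
  return acc / n;
}

static int make_offsets(int connectivity, int off[26][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off[n][0] = dx; off[n][1] = dy; off[n][2] = dz; ++n;
      }
  return n;
}

// Label connected components of a binary volume; returns 0 for background,
// 1..K for components (K in decreasing-discovery order, not sorted by size).
// [[Rcpp::export]]
IntegerVector cppLabelComponents(LogicalVector mask, IntegerVector dim,
                                 int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int off[26][3];
  int noff = make_offsets(connectivity, off);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s0 = 0; s0 < n; ++s0) {
    if (!mask[s0] || lab[s0]) continue;
    ++cur;
    lab[s0] = cur;
    stack.clear();
    stack.push_back(s0);
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      for (int t = 0; t < noff; ++t) {
        int xx = x + off[t][0], yy = y + off[t][1], zz = z + off[t][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t w = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Zero-padded 1D convolution along axis (0,1,2) of a 3D volume. The kernel
// is applied centred: out[i] = sum_t k[t] * vol[i + t - (len-1)/2].
// [[Rcpp::export]]
NumericVector cppConvAxis(NumericVector vol, IntegerVector dim,
                          NumericVector kernel, int axis) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int kl = kernel.size(), hw = (kl - 1) / 2;
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vol.begin();
  const double* k = kernel.begin();
  double* o = out.begin();
  size_t stride = (axis == 0) ? 1 : (axis == 1 ? (size_t)nx : (size_t)nx * ny);
  int alen = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        size_t base = x + (size_t)nx * (y + (size_t)ny * z);
        for (int i = 0; i < alen; ++i) {
          double acc = 0.0;
          int t0 = std::max(0, hw - i), t1 = std::min(kl, alen + hw - i);
          const double* line = v + base;
          for (int t = t0; t < t1; ++t) acc += k[t] * line[(size_t)(i + t - hw) * stride];
          o[base + (size_t)i * stride] = acc;
        }
      }
  return out;
}

// Binary dilation/erosion with an arbitrary structuring element given as a
// matrix of integer voxel offsets (N x 3).
// [[Rcpp::export]]
LogicalVector cppMorph(LogicalVector mask, IntegerVector dim,
                       IntegerMatrix offsets, int dilate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  int noff = offsets.nrow();
  for (size_t v = 0; v < n; ++v) {
    int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
    bool acc = dilate ? false : true;
    for (int t = 0; t < noff; ++t) {
      int xx = x + offsets(t,0), yy = y + offsets(t,1), zz = z + offsets(t,2);
      bool val;
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        val = false;  // outside field of view is background
      else
        val = mask[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      if (dilate) { if (val) { acc = true; break; } }
      else        { if (!val) { acc = false; break; } }
    }
    out[v] = acc;
  }
  return out;
}

// E-step of the prior-weighted Gaussian mixture: responsibilities of each
// Gaussian at each voxel and the total log-likelihood.
// prior: n x C class prior matrix; gcls: class index (0-based) per Gaussian.
// [[Rcpp::export]]
List cppEmResp(NumericVector y, NumericMatrix prior, NumericVector mu,
               NumericVector var, NumericVector w, IntegerVector gcls) {
  int n = y.size(), G = mu.size();
  NumericMatrix resp(n, G);
  std::vector<double> norm(G), inv2v(G);
  for (int g = 0; g < G; ++g) {
    norm[g] = w[g] / std::sqrt(2.0 * M_PI * var[g]);
    inv2v[g] = 0.5 / var[g];
  }
  double ll = 0.0;
  const double tiny = 1e-300;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int g = 0; g < G; ++g) {
      double d = y[i] - mu[g];
      double p = prior(i, gcls[g]) * norm[g] * std::exp(-d * d * inv2v[g]);
      resp(i, g) = p;
      s += p;
    }
    if (s < tiny) {
      // likelihood underflow: fall back to the prior (weights within class
      // sum to 1 and class priors sum to 1, so the row stays normalized)
      for (int g = 0; g < G; ++g) resp(i, g) = prior(i, gcls[g]) * w[g];
      ll += std::log(tiny);
      continue;
    }
    ll += std::log(s);
    double inv = 1.0 / s;
    for (int g = 0; g < G; ++g) resp(i, g) *= inv;
  }
  return List::create(_["resp"] = resp, _["loglik"] = ll);
}

// Maximum suprathreshold cluster size of a one-tailed two-sample t map for
// each row of a permutation matrix. Y: V x n matrix of masked voxel data
// (V masked voxels, n subjects); perms: P x n matrix of 0/1 labels (1 =
// "control" group whose mean enters positively); tcrit: one-tailed t
// threshold; maskIdx: 0-based linear indices of the masked voxels in the
// full 3D volume of dims `dim`.
// [[Rcpp::export]]
IntegerVector cppPermMaxCluster(NumericMatrix Y, IntegerMatrix perms,
                                double tcrit, IntegerVector maskIdx,
                                IntegerVector dim, int connectivity) {
  int V = Y.nrow(), n = Y.ncol(), P = perms.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector maxsz(P);
  std::vector<char> mask(nvox);
  std::vector<int> lab(nvox);
  std::vector<size_t> stack;
  int off[26][3];
  int noff = make_offsets(connectivity, off);
  std::vector<int> idx1, idx0;
  for (int p = 0; p < P; ++p) {
    idx1.clear(); idx0.clear();
    for (int j = 0; j < n; ++j)
      (perms(p, j) == 1 ? idx1 : idx0).push_back(j);
    int n1 = idx1.size(), n0 = idx0.size();
    double fac = std::sqrt(1.0 / n1 + 1.0 / n0);
    int df = n - 2;
    std::fill(mask.begin(), mask.end(), 0);
    for (int v = 0; v < V; ++v) {
      double s1 = 0, q1 = 0, s0 = 0, q0 = 0;
      for (int j : idx1) { double x = Y(v, j); s1 += x; q1 += x * x; }
      for (int j : idx0) { double x = Y(v, j); s0 += x; q0 += x * x; }
      double m1 = s1 / n1, m0 = s0 / n0;
      double ss = (q1 - n1 * m1 * m1) + (q0 - n0 * m0 * m0);
      double sp = std::sqrt(ss / df);
      if (sp <= 0) continue;
      double t = (m1 - m0) / (sp * fac);
      if (t > tcrit) mask[maskIdx[v]] = 1;
    }
    // max component size by flood fill over masked voxels only
    std::fill(lab.begin(), lab.end(), 0);
    int best = 0;
    for (int v = 0; v < V; ++v) {
      size_t s0i = maskIdx[v];
      if (!mask[s0i] || lab[s0i]) continue;
      int sz = 1;
      lab[s0i] = 1;
      stack.clear(); stack.push_back(s0i);
      while (!stack.empty()) {
        size_t u = stack.back(); stack.pop_back();
        int x = u % nx, y = (u / nx) % ny, z = u / ((size_t)nx * ny);
        for (int t = 0; t < noff; ++t) {
          int xx = x + off[t][0], yy = y + off[t][1], zz = z + off[t][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          size_t wv = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (mask[wv] && !lab[wv]) { lab[wv] = 1; stack.push_back(wv); ++sz; }
        }
      }
      if (sz > best) best = sz;
    }
    maxsz[p] = best;
  }
  return maxsz;
}
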