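// Low-level 3D grid algorithms shared by the segmentation and feature code.
// Arrays are R arrays in column-major order, dim = (n1, n2, n3); all
// neighbourhood definitions are axis-symmetric so the code is agnostic to
// which axis is "z".

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double DT_INF = 1e30;

// ---------------------------------------------------------------------------
// 1D squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher). f is the input cost, d the output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> z;
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest FALSE voxel.
// Voxels outside the array are NOT counted as background.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? DT_INF : 0.0;

  std::vector<double> f, d;
  // pass along axis 1 (stride 1)
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, n1);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // axis 2 (stride n1)
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, n2);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3 (stride n1*n2)
  f.resize(n3); d.resize(n3);
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = out[base + s3 * k];
      dt1d(f, d, n3);
      for (int k = 0; k < n3; ++k) out[base + s3 * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// neighbour offset table
static void neighbour_offsets(int n1, int n2, int conn,
                              std::vector<R_xlen_t>& off,
                              std::vector<int>& d1,
                              std::vector<int>& d2,
                              std::vector<int>& d3) {
  off.clear(); d1.clear(); d2.clear(); d3.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && m > 1) continue;
        off.push_back((R_xlen_t)dx + (R_xlen_t)n1 * (dy + (R_xlen_t)n2 * dz));
        d1.push_back(dx); d2.push_back(dy); d3.push_back(dz);
      }
}

// Connected component labelling (6 or 26), labels 1..N in scan order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(n);
  std::vector<R_xlen_t> off; std::vector<int> d1, d2, d3;
  neighbour_offsets(n1, n2, connectivity, off, d1, d2, d3);
  const int nb = (int)off.size();
  std::vector<R_xlen_t> stack;
  int lab = 0;
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p] || out[p] != 0) continue;
    ++lab;
    out[p] = lab;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      int x = (int)(q % n1);
      int y = (int)((q / n1) % n2);
      int z = (int)(q / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < nb; ++t) {
        int xx = x + d1[t], yy = y + d2[t], zz = z + d3[t];
        if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
          continue;
        R_xlen_t r = q + off[t];
        if (mask[r] && out[r] == 0) {
          out[r] = lab;
          stack.push_back(r);
        }
      }
    }
  }
  out.attr("n_labels") = lab;
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm, 6-connectivity). marker must satisfy marker <= mask everywhere.
// [[Rcpp::export(name = ".reconstruct_gray_cpp")]]
NumericVector reconstruct_gray_cpp(NumericVector marker, NumericVector mask,
                                   IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector J = clone(marker);
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;

  // forward raster scan: predecessors (x-1, y-1, z-1 directions)
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        R_xlen_t p = x + s2 * y + s3 * z;
        double m = J[p];
        if (x > 0 && J[p - s1] > m) m = J[p - s1];
        if (y > 0 && J[p - s2] > m) m = J[p - s2];
        if (z > 0 && J[p - s3] > m) m = J[p - s3];
        if (m > mask[p]) m = mask[p];
        J[p] = m;
      }
  // backward raster scan + queue initialisation
  std::queue<R_xlen_t> fifo;
  for (int z = n3 - 1; z >= 0; --z)
    for (int y = n2 - 1; y >= 0; --y)
      for (int x = n1 - 1; x >= 0; --x) {
        R_xlen_t p = x + s2 * y + s3 * z;
        double m = J[p];
        if (x < n1 - 1 && J[p + s1] > m) m = J[p + s1];
        if (y < n2 - 1 && J[p + s2] > m) m = J[p + s2];
        if (z < n3 - 1 && J[p + s3] > m) m = J[p + s3];
        if (m > mask[p]) m = mask[p];
        J[p] = m;
        // queue if a successor could still grow
        bool push = false;
        if (x < n1 - 1 && J[p + s1] < J[p] && J[p + s1] < mask[p + s1]) push = true;
        if (!push && y < n2 - 1 && J[p + s2] < J[p] && J[p + s2] < mask[p + s2]) push = true;
        if (!push && z < n3 - 1 && J[p + s3] < J[p] && J[p + s3] < mask[p + s3]) push = true;
        if (push) fifo.push(p);
      }
  const int DX[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, 1, -1};
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int x = (int)(p % n1);
    int y = (int)((p / n1) % n2);
    int z = (int)(p / s3);
    for (int t = 0; t < 6; ++t) {
      int xx = x + DX[t], yy = y + DY[t], zz = z + DZ[t];
      if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
        continue;
      R_xlen_t q = xx + s2 * yy + s3 * zz;
      if (J[q] < J[p] && J[q] < mask[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding on a height map (flooded
// from high values downwards -- pass the distance map directly). Ties are
// broken by linear voxel index, so the result is deterministic.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector height, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(n);

  struct Node {
    double h;
    R_xlen_t idx;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.h != b.h) return a.h < b.h;   // max-heap on height
      return a.idx > b.idx;               // then smallest index first
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;

  for (R_xlen_t p = 0; p < n; ++p) {
    if (markers[p] > 0 && mask[p]) {
      out[p] = markers[p];
      pq.push({height[p], p});
    }
  }
  const int DX[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, 1, -1};
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    R_xlen_t p = nd.idx;
    int lab = out[p];
    int x = (int)(p % n1);
    int y = (int)((p / n1) % n2);
    int z = (int)(p / s3);
    for (int t = 0; t < 6; ++t) {
      int xx = x + DX[t], yy = y + DY[t], zz = z + DZ[t];
      if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
        continue;
      R_xlen_t q = xx + s2 * yy + s3 * zz;
      if (mask[q] && out[q] == 0) {
        out[q] = lab;
        pq.push({height[q], q});
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness: per foreground voxel, the diameter (in voxels) of the
// largest inscribed sphere that contains it. Spheres are painted from the
// ridge of the distance map (local maxima of the EDT); 2*EDT is used as a
// lower bound everywhere so no voxel is left uncovered.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector d2 = edt_sq_cpp(mask, dim);
  std::vector<double> r(n);
  for (R_xlen_t i = 0; i < n; ++i) r[i] = std::sqrt(d2[i]);

  // ridge voxels: EDT is a 26-neighbourhood maximum (plateaus included)
  std::vector<R_xlen_t> off; std::vector<int> o1, o2, o3;
  neighbour_offsets(n1, n2, 26, off, o1, o2, o3);
  std::vector<R_xlen_t> ridge;
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    int x = (int)(p % n1);
    int y = (int)((p / n1) % n2);
    int z = (int)(p / ((R_xlen_t)n1 * n2));
    bool is_max = true;
    for (size_t t = 0; t < off.size() && is_max; ++t) {
      int xx = x + o1[t], yy = y + o2[t], zz = z + o3[t];
      if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
        continue;
      if (r[p + off[t]] > r[p]) is_max = false;
    }
    if (is_max) ridge.push_back(p);
  }
  std::sort(ridge.begin(), ridge.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (r[a] != r[b]) return r[a] > r[b];
    return a < b;
  });

  NumericVector thick(n);
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t ridx = 0; ridx < (R_xlen_t)ridge.size(); ++ridx) {
    R_xlen_t p = ridge[ridx];
    double rp = r[p];
    double diam = 2.0 * rp;
    if (thick[p] >= diam) continue;  // already inside a sphere at least as big
    int x = (int)(p % n1);
    int y = (int)((p / n1) % n2);
    int z = (int)(p / s3);
    int ri = (int)std::floor(rp);
    double rp2 = rp * rp;
    for (int dz = -ri; dz <= ri; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= n3) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= n2) continue;
        double dd = (double)dz * dz + (double)dy * dy;
        if (dd > rp2) continue;
        int rx = (int)std::floor(std::sqrt(rp2 - dd));
        int x0 = std::max(0, x - rx), x1 = std::min(n1 - 1, x + rx);
        R_xlen_t base = (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * zz);
        for (int xx = x0; xx <= x1; ++xx) {
          R_xlen_t q = base + xx;
          if (thick[q] < diam) thick[q] = diam;
        }
      }
    }
  }
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p]) { thick[p] = 0.0; continue; }
    double lb = 2.0 * r[p];
    if (thick[p] < lb) thick[p] = lb;
  }
  return thick;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflecting boundary. sigma in voxels.
// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericVector gaussian_blur_cpp(NumericVector vol, IntegerVector dim,
                                double sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  if (sigma <= 0) return clone(vol);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + rad];
  }
  for (double& k : kern) k /= s;

  NumericVector a = clone(vol);
  NumericVector b(a.size());
  const R_xlen_t strides[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
  const int sizes[3] = {n1, n2, n3};
  for (int ax = 0; ax < 3; ++ax) {
    const int m = sizes[ax];
    const R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    const int u = sizes[(ax + 1) % 3], v = sizes[(ax + 2) % 3];
    const R_xlen_t su = strides[(ax + 1) % 3], sv = strides[(ax + 2) % 3];
    for (int j = 0; j < v; ++j)
      for (int i = 0; i < u; ++i) {
        R_xlen_t base = su * i + sv * j;
        for (int q = 0; q < m; ++q) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int qq = q + t;
            if (qq < 0) qq = -qq - 1;
            if (qq >= m) qq = 2 * m - qq - 1;
            acc += kern[t + rad] * a[base + st * qq];
          }
          b[base + st * q] = acc;
        }
      }
    std::swap(a, b);
  }
  return a;
}

// ---------------------------------------------------------------------------
// 3D median filter over a cubic (2r+1)^3 window clipped at the borders.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericVector median_filter_cpp(NumericVector vol, IntegerVector dim, int rad) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  if (rad <= 0) return clone(vol);
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * rad + 1) * (2 * rad + 1) * (2 * rad + 1));
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        buf.clear();
        for (int dz = -rad; dz <= rad; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= n3) continue;
          for (int dy = -rad; dy <= rad; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= n2) continue;
            R_xlen_t base = (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * zz);
            for (int dx = -rad; dx <= rad; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= n1) continue;
              buf.push_back(vol[base + xx]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          med = 0.5 * (med + lo);
        }
        out[x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z)] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at arbitrary (0-based) voxel coordinates; points
// outside the grid evaluate to 0.
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[i] = 0.0;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    int x1 = std::min(x0 + 1, n1 - 1);
    int y1 = std::min(y0 + 1, n2 - 1);
    int z1 = std::min(z0 + 1, n3 - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double c000 = vol[x0 + s2 * y0 + s3 * z0];
    double c100 = vol[x1 + s2 * y0 + s3 * z0];
    double c010 = vol[x0 + s2 * y1 + s3 * z0];
    double c110 = vol[x1 + s2 * y1 + s3 * z0];
    double c001 = vol[x0 + s2 * y0 + s3 * z1];
    double c101 = vol[x1 + s2 * y0 + s3 * z1];
    double c011 = vol[x0 + s2 * y1 + s3 * z1];
    double c111 = vol[x1 + s2 * y1 + s3 * z1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Coordinates (0-based) of foreground voxels with at least one 6-neighbour
// background voxel; array-border foreground counts as boundary.
// [[Rcpp::export(name = ".boundary_voxels_cpp")]]
IntegerMatrix boundary_voxels_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  std::vector<int> xs, ys, zs;
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        R_xlen_t p = x + s2 * y + s3 * z;
        if (!mask[p]) continue;
        bool bd = (x == 0 || x == n1 - 1 || y == 0 || y == n2 - 1 ||
                   z == 0 || z == n3 - 1);
        if (!bd) {
          bd = !mask[p - 1] || !mask[p + 1] || !mask[p - s2] ||
               !mask[p + s2] || !mask[p - s3] || !mask[p + s3];
        }
        if (bd) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}
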