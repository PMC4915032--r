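#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel centres sit at (i + 0.5) * spacing, 0-based i; all lengths in micrometres.
// Arrays are indexed [y, x, z] to match R's matrix convention for images.

static inline double sq(double v) { return v * v; }

// Squared distance from point p to segment a-b.
static double dist2_point_segment(double px, double py, double pz,
                                  double ax, double ay, double az,
                                  double bx, double by, double bz) {
  double abx = bx - ax, aby = by - ay, abz = bz - az;
  double apx = px - ax, apy = py - ay, apz = pz - az;
  double len2 = abx * abx + aby * aby + abz * abz;
  double t = len2 > 0 ? (apx * abx + apy * aby + apz * abz) / len2 : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  return sq(px - (ax + t * abx)) + sq(py - (ay + t * aby)) + sq(pz - (az + t * abz));
}

// Occupancy of a union of capsules (segments with radius) and spheres.
// segs: n x 7 (x1 y1 z1 x2 y2 z2 r), sph: m x 4 (x y z r).
// The z axis is sampled `z_aa` times per cell and the inside-fraction
// stored (anti-aliasing: the z grid is coarser than the lateral grid, and
// binary sampling would alias structures thinner than one z cell).
// Overlapping primitives combine by max of their fractions.
// [[Rcpp::export]]
NumericVector cpp_rasterize(int ny, int nx, int nz,
                            double dx, double dy, double dz,
                            NumericMatrix segs, NumericMatrix sph,
                            int z_aa = 4) {
  NumericVector out(static_cast<R_xlen_t>(ny) * nx * nz);
  out.attr("dim") = IntegerVector::create(ny, nx, nz);
  double* o = REAL(out);

  auto mark_box = [&](double x0, double x1, double y0, double y1,
                      double z0, double z1, auto&& inside) {
    int ix0 = std::max(0, (int)std::floor(x0 / dx - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil(x1 / dx - 0.5));
    int iy0 = std::max(0, (int)std::floor(y0 / dy - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil(y1 / dy - 0.5));
    int iz0 = std::max(0, (int)std::floor(z0 / dz - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil(z1 / dz - 0.5));
    double frac = 1.0 / z_aa;
    for (int k = iz0; k <= iz1; ++k) {
      for (int j = ix0; j <= ix1; ++j) {
        double px = (j + 0.5) * dx;
        for (int i = iy0; i <= iy1; ++i) {
          double py = (i + 0.5) * dy;
          double cov = 0.0;
          for (int s = 0; s < z_aa; ++s) {
            double pz = (k + (s + 0.5) / z_aa) * dz;
            if (inside(px, py, pz)) cov += frac;
          }
          R_xlen_t idx = (R_xlen_t)k * ny * nx + (R_xlen_t)j * ny + i;
          if (cov > o[idx]) o[idx] = cov;
        }
      }
    }
  };

  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5), r = segs(s, 6);
    double r2 = r * r;
    mark_box(std::min(ax, bx) - r, std::max(ax, bx) + r,
             std::min(ay, by) - r, std::max(ay, by) + r,
             std::min(az, bz) - r, std::max(az, bz) + r,
             [&](double px, double py, double pz) {
               return dist2_point_segment(px, py, pz, ax, ay, az, bx, by, bz) <= r2;
             });
  }
  for (int s = 0; s < sph.nrow(); ++s) {
    double cx = sph(s, 0), cy = sph(s, 1), cz = sph(s, 2), r = sph(s, 3);
    double r2 = r * r;
    mark_box(cx - r, cx + r, cy - r, cy + r, cz - r, cz + r,
             [&](double px, double py, double pz) {
               return sq(px - cx) + sq(py - cy) + sq(pz - cz) <= r2;
             });
  }
  return out;
}

// Separable convolution along one axis with zero padding. Along y the data
// is contiguous; along x and z whole contiguous columns/planes are
// accumulated (AXPY-style) so the inner loops stay cache-friendly. Lateral
// passes skip all-zero z-planes (rasterized occupancy is sparse in z).
static void conv_axis(std::vector<double>& a, int ny, int nx, int nz,
                      const NumericVector& k, int axis,
                      const std::vector<char>& zlive) {
  int half = ((int)k.size() - 1) / 2;
  std::vector<double> tmp(a.size(), 0.0);
  R_xlen_t plane = (R_xlen_t)ny * nx;
  if (axis == 0) {
    for (int z = 0; z < nz; ++z) {
      if (!zlive[z]) continue;
      for (int x = 0; x < nx; ++x) {
        const double* in = &a[(R_xlen_t)z * plane + (R_xlen_t)x * ny];
        double* out = &tmp[(R_xlen_t)z * plane + (R_xlen_t)x * ny];
        for (int t = -half; t <= half; ++t) {
          double w = k[t + half];
          int y0 = std::max(0, -t), y1 = std::min(ny, ny - t);
          const double* src = in + t;
          for (int y = y0; y < y1; ++y) out[y] += w * src[y];
        }
      }
    }
  } else if (axis == 1) {
    for (int z = 0; z < nz; ++z) {
      if (!zlive[z]) continue;
      for (int x = 0; x < nx; ++x) {
        double* out = &tmp[(R_xlen_t)z * plane + (R_xlen_t)x * ny];
        for (int t = -half; t <= half; ++t) {
          int xs = x + t;
          if (xs < 0 || xs >= nx) continue;
          double w = k[t + half];
          const double* src = &a[(R_xlen_t)z * plane + (R_xlen_t)xs * ny];
          for (int y = 0; y < ny; ++y) out[y] += w * src[y];
        }
      }
    }
  } else {
    for (int z = 0; z < nz; ++z) {
      double* out = &tmp[(R_xlen_t)z * plane];
      for (int t = -half; t <= half; ++t) {
        int zs = z + t;
        if (zs < 0 || zs >= nz || !zlive[zs]) continue;
        double w = k[t + half];
        const double* src = &a[(R_xlen_t)zs * plane];
        for (R_xlen_t i = 0; i < plane; ++i) out[i] += w * src[i];
      }
    }
  }
  a.swap(tmp);
}

// Separable 3D convolution with zero padding; ky/kx/kz are odd-length kernels.
// [[Rcpp::export]]
NumericVector cpp_sepconv3(NumericVector vol, NumericVector ky,
                           NumericVector kx, NumericVector kz) {
  IntegerVector d = vol.attr("dim");
  int ny = d[0], nx = d[1], nz = d[2];
  std::vector<double> a(vol.begin(), vol.end());
  R_xlen_t plane = (R_xlen_t)ny * nx;
  std::vector<char> zlive(nz, 0);
  for (int z = 0; z < nz; ++z) {
    const double* p = &a[(R_xlen_t)z * plane];
    for (R_xlen_t i = 0; i < plane; ++i)
      if (p[i] != 0.0) { zlive[z] = 1; break; }
  }
  if (ky.size() > 1) conv_axis(a, ny, nx, nz, ky, 0, zlive);
  if (kx.size() > 1) conv_axis(a, ny, nx, nz, kx, 1, zlive);
  if (kz.size() > 1) conv_axis(a, ny, nx, nz, kz, 2, zlive);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(ny, nx, nz);
  return out;
}

// Block-mean downsampling by integer factors (fy, fx, fz); dims must divide.
// [[Rcpp::export]]
NumericVector cpp_downsample3(NumericVector vol, int fy, int fx, int fz) {
  IntegerVector d = vol.attr("dim");
  int ny = d[0], nx = d[1], nz = d[2];
  int oy = ny / fy, ox = nx / fx, oz = nz / fz;
  NumericVector out(static_cast<R_xlen_t>(oy) * ox * oz);
  out.attr("dim") = IntegerVector::create(oy, ox, oz);
  const double* v = REAL(vol);
  double* o = REAL(out);
  double norm = 1.0 / ((double)fy * fx * fz);
  R_xlen_t plane = (R_xlen_t)ny * nx;
  for (int z = 0; z < oz; ++z)
    for (int x = 0; x < ox; ++x)
      for (int y = 0; y < oy; ++y) {
        double acc = 0;
        for (int kz2 = 0; kz2 < fz; ++kz2)
          for (int kx2 = 0; kx2 < fx; ++kx2)
            for (int ky2 = 0; ky2 < fy; ++ky2)
              acc += v[(R_xlen_t)(z * fz + kz2) * plane +
                       (R_xlen_t)(x * fx + kx2) * ny + (y * fy + ky2)];
        o[(R_xlen_t)z * oy * ox + (R_xlen_t)x * oy + y] = acc * norm;
      }
  return out;
}

// Explicit finite-difference solver for 1D diffusion along a spine neck
// (length L, cross-section A, n cells) coupling a Dirichlet reservoir
// (concentration 1 at x=0) to a well-mixed head compartment (volume V,
// initial concentration 0) at x=L. Returns head concentration sampled at
// n_out uniformly spaced times up to t_end.
// [[Rcpp::export]]
List cpp_diffusion_recovery(double V, double L, double A, double D,
                            double dt, double t_end, int n_cells, int n_out) {
  double dx = L / n_cells;
  long n_steps = (long)std::ceil(t_end / dt);
  std::vector<double> u(n_cells, 0.0), un(n_cells);
  double head = 0.0;
  NumericVector times(n_out), conc(n_out);
  long stride = std::max(1L, n_steps / n_out);
  double r = D * dt / (dx * dx);
  int out_i = 0;
  for (long step = 1; step <= n_steps && out_i < n_out; ++step) {
    for (int i = 0; i < n_cells; ++i) {
      double left = (i == 0) ? 1.0 : u[i - 1];
      double right = (i == n_cells - 1) ? head : u[i + 1];
      un[i] = u[i] + r * (left - 2.0 * u[i] + right);
    }
    // flux into the head from the last neck cell
    double flux = D * A * (u[n_cells - 1] - head) / dx;
    head += flux * dt / V;
    u.swap(un);
    if (step % stride == 0 || step == n_steps) {
      times[out_i] = step * dt;
      conc[out_i] = head;
      ++out_i;
    }
  }
  if (out_i < n_out) {
    times = Rcpp::head(times, out_i);
    conc = Rcpp::head(conc, out_i);
  }
  return List::create(_["time"] = times, _["concentration"] = conc);
}

// Dijkstra over an 8-connected pixel grid. cost: ny x nx per-pixel traversal
// cost (<= 0 or NA means blocked); edge weight = step length * mean endpoint
// cost. Returns geodesic distance and parent index (1-based, 0 at source /
// unreachable). source is 1-based (row, col).
// [[Rcpp::export]]
List cpp_grid_dijkstra(NumericMatrix cost, int src_row, int src_col) {
  int ny = cost.nrow(), nx = cost.ncol();
  R_xlen_t n = (R_xlen_t)ny * nx;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, 0);
  auto idx = [&](int r, int c) { return (R_xlen_t)c * ny + r; };
  auto blocked = [&](int r, int c) {
    double v = cost(r, c);
    return NumericMatrix::is_na(v) || v <= 0;
  };
  int sr = src_row - 1, sc = src_col - 1;
  if (sr < 0 || sr >= ny || sc < 0 || sc >= nx) stop("source outside image");
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  if (!blocked(sr, sc)) {
    dist[idx(sr, sc)] = 0.0;
    pq.push(Node(0.0, idx(sr, sc)));
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double dl[8] = {M_SQRT2, 1, M_SQRT2, 1, 1, M_SQRT2, 1, M_SQRT2};
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    int uc = (int)(u / ny), ur = (int)(u % ny);
    for (int m = 0; m < 8; ++m) {
      int vr = ur + dr[m], vc = uc + dc[m];
      if (vr < 0 || vr >= ny || vc < 0 || vc >= nx || blocked(vr, vc)) continue;
      double w = dl[m] * 0.5 * (cost(ur, uc) + cost(vr, vc));
      R_xlen_t v = idx(vr, vc);
      if (dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        parent[v] = (int)(u + 1);
        pq.push(Node(dist[v], v));
      }
    }
  }
  NumericVector dmat(dist.begin(), dist.end());
  dmat.attr("dim") = IntegerVector::create(ny, nx);
  IntegerVector pmat(parent.begin(), parent.end());
  pmat.attr("dim") = IntegerVector::create(ny, nx);
  return List::create(_["dist"] = dmat, _["parent"] = pmat);
}
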