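#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra on a rectilinear scalar grid.
//
// Each grid cell is split into 6 tetrahedra (Kuhn decomposition around the
// main diagonal c0-c6). The decomposition is translation invariant, so face
// diagonals agree between neighbouring cells and the extracted surface of a
// superlevel set {f >= level} is watertight wherever the set does not touch
// the evaluation domain. Edge vertices are merged through a global edge key,
// which makes open-edge counting and connected-component labelling exact.
// ---------------------------------------------------------------------------

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

static const int COFF[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

struct IsoMesh {
  std::vector<double> vx, vy, vz;            // merged vertex coordinates (mm)
  std::vector<int> fa, fb, fc;               // triangle vertex indices, 0-based
  std::unordered_map<uint64_t, int> emap;    // grid-edge key -> vertex index
  uint64_t ntot;                             // total grid nodes (for keys)

  int edge_vertex(uint64_t ga, uint64_t gb, double fA, double fB,
                  const double* pA, const double* pB, double level) {
    // canonicalise so both cells interpolate the edge identically
    if (gb < ga) {
      std::swap(ga, gb); std::swap(fA, fB);
      const double* tmp = pA; pA = pB; pB = tmp;
    }
    uint64_t key = ga * ntot + gb;
    std::unordered_map<uint64_t, int>::iterator it = emap.find(key);
    if (it != emap.end()) return it->second;
    double t = (level - fA) / (fB - fA);
    int id = (int) vx.size();
    vx.push_back(pA[0] + t * (pB[0] - pA[0]));
    vy.push_back(pA[1] + t * (pB[1] - pA[1]));
    vz.push_back(pA[2] + t * (pB[2] - pA[2]));
    emap[key] = id;
    return id;
  }

  void emit(int e0, int e1, int e2, const double* ref) {
    if (e0 == e1 || e1 == e2 || e0 == e2) return;  // degenerate, zero area
    double ux = vx[e1] - vx[e0], uy = vy[e1] - vy[e0], uz = vz[e1] - vz[e0];
    double wx = vx[e2] - vx[e0], wy = vy[e2] - vy[e0], wz = vz[e2] - vz[e0];
    double nx = uy * wz - uz * wy;
    double ny = uz * wx - ux * wz;
    double nz = ux * wy - uy * wx;
    // orient the normal away from the high-dose side (outward for {f >= L})
    if (nx * ref[0] + ny * ref[1] + nz * ref[2] < 0.0) std::swap(e1, e2);
    fa.push_back(e0); fb.push_back(e1); fc.push_back(e2);
  }
};

static void build_isosurface(const double* val, int nx, int ny, int nz,
                             double sx, double sy, double sz,
                             double ox, double oy, double oz,
                             double level, const int* dom, IsoMesh& M) {
  M.ntot = (uint64_t) nx * (uint64_t) ny * (uint64_t) nz;
  const double eps = 1e-9 * (1.0 + std::fabs(level));

  uint64_t g[8];
  double f[8], P[8][3], ref[3];
  bool in[8];

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        bool usable = true;
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + COFF[c][0], cj = j + COFF[c][1], ck = k + COFF[c][2];
          uint64_t gi = (uint64_t) ci + (uint64_t) nx *
            ((uint64_t) cj + (uint64_t) ny * (uint64_t) ck);
          if (dom && !dom[gi]) { usable = false; break; }
          double v = val[gi];
          if (v == level) v = level + eps;   // break exact-level degeneracy
          g[c] = gi; f[c] = v;
          in[c] = (v >= level);
          nin += in[c];
          P[c][0] = ox + ci * sx;
          P[c][1] = oy + cj * sy;
          P[c][2] = oz + ck * sz;
        }
        if (!usable || nin == 0 || nin == 8) continue;

        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (in[T[c]]) ins[ni++] = T[c]; else outs[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;

          if (ni == 1) {
            int a = ins[0];
            int e0 = M.edge_vertex(g[a], g[outs[0]], f[a], f[outs[0]], P[a], P[outs[0]], level);
            int e1 = M.edge_vertex(g[a], g[outs[1]], f[a], f[outs[1]], P[a], P[outs[1]], level);
            int e2 = M.edge_vertex(g[a], g[outs[2]], f[a], f[outs[2]], P[a], P[outs[2]], level);
            for (int d = 0; d < 3; ++d)
              ref[d] = (P[outs[0]][d] + P[outs[1]][d] + P[outs[2]][d]) / 3.0 - P[a][d];
            M.emit(e0, e1, e2, ref);
          } else if (ni == 3) {
            int o = outs[0];
            int e0 = M.edge_vertex(g[o], g[ins[0]], f[o], f[ins[0]], P[o], P[ins[0]], level);
            int e1 = M.edge_vertex(g[o], g[ins[1]], f[o], f[ins[1]], P[o], P[ins[1]], level);
            int e2 = M.edge_vertex(g[o], g[ins[2]], f[o], f[ins[2]], P[o], P[ins[2]], level);
            for (int d = 0; d < 3; ++d)
              ref[d] = P[o][d] - (P[ins[0]][d] + P[ins[1]][d] + P[ins[2]][d]) / 3.0;
            M.emit(e0, e1, e2, ref);
          } else {  // ni == 2: quad split into two triangles
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eAC = M.edge_vertex(g[A], g[C], f[A], f[C], P[A], P[C], level);
            int eAD = M.edge_vertex(g[A], g[D], f[A], f[D], P[A], P[D], level);
            int eBC = M.edge_vertex(g[B], g[C], f[B], f[C], P[B], P[C], level);
            int eBD = M.edge_vertex(g[B], g[D], f[B], f[D], P[B], P[D], level);
            for (int d = 0; d < 3; ++d)
              ref[d] = 0.5 * (P[C][d] + P[D][d]) - 0.5 * (P[A][d] + P[B][d]);
            M.emit(eAC, eAD, eBD, ref);
            M.emit(eAC, eBD, eBC, ref);
          }
        }
      }
    }
  }
}

struct UnionFind {
  std::vector<int> p;
  UnionFind(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

static void mesh_stats(const IsoMesh& M, double cx, double cy, double cz,
                       double& area, double& vol, int& open_edges, int& ncomp) {
  area = 0.0; vol = 0.0;
  size_t nf = M.fa.size();
  size_t nv = M.vx.size();
  std::unordered_map<uint64_t, int> ecount;
  ecount.reserve(nf * 2);
  UnionFind uf((int) nv);
  std::vector<char> used(nv, 0);

  for (size_t q = 0; q < nf; ++q) {
    int a = M.fa[q], b = M.fb[q], c = M.fc[q];
    double ax = M.vx[a] - cx, ay = M.vy[a] - cy, az = M.vz[a] - cz;
    double bx = M.vx[b] - cx, by = M.vy[b] - cy, bz = M.vz[b] - cz;
    double qx = M.vx[c] - cx, qy = M.vy[c] - cy, qz = M.vz[c] - cz;
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double wx = qx - ax, wy = qy - ay, wz = qz - az;
    double nxx = uy * wz - uz * wy;
    double nyy = uz * wx - ux * wz;
    double nzz = ux * wy - uy * wx;
    area += 0.5 * std::sqrt(nxx * nxx + nyy * nyy + nzz * nzz);
    // divergence theorem: signed volume of tetrahedron (0, a, b, c)
    vol += (ax * (by * qz - bz * qy)
          - ay * (bx * qz - bz * qx)
          + az * (bx * qy - by * qx)) / 6.0;

    int e[3][2] = {{a, b}, {b, c}, {c, a}};
    for (int s = 0; s < 3; ++s) {
      uint64_t lo = (uint64_t) std::min(e[s][0], e[s][1]);
      uint64_t hi = (uint64_t) std::max(e[s][0], e[s][1]);
      ecount[lo * (uint64_t) nv + hi] += 1;
    }
    uf.unite(a, b); uf.unite(b, c);
    used[a] = used[b] = used[c] = 1;
  }

  open_edges = 0;
  for (std::unordered_map<uint64_t, int>::iterator it = ecount.begin();
       it != ecount.end(); ++it)
    if (it->second != 2) ++open_edges;

  std::unordered_map<int, int> roots;
  for (size_t v = 0; v < nv; ++v)
    if (used[v]) roots[uf.find((int) v)] = 1;
  ncomp = (int) roots.size();
}

static const int* domain_ptr(Nullable<IntegerVector> domain, IntegerVector& keep) {
  if (domain.isNull()) return 0;
  keep = domain.get();
  return INTEGER(keep);
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector values, IntegerVector dims,
                    NumericVector spacing, NumericVector origin,
                    double level, Nullable<IntegerVector> domain,
                    bool return_mesh) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector keep;
  const int* dom = domain_ptr(domain, keep);

  IsoMesh M;
  build_isosurface(REAL(values), nx, ny, nz,
                   spacing[0], spacing[1], spacing[2],
                   origin[0], origin[1], origin[2], level, dom, M);

  double cx = origin[0] + 0.5 * (nx - 1) * spacing[0];
  double cy = origin[1] + 0.5 * (ny - 1) * spacing[1];
  double cz = origin[2] + 0.5 * (nz - 1) * spacing[2];
  double area, vol;
  int open_edges, ncomp;
  mesh_stats(M, cx, cy, cz, area, vol, open_edges, ncomp);

  List out = List::create(
    _["area"] = area, _["volume"] = vol,
    _["open_edges"] = open_edges, _["n_components"] = ncomp,
    _["n_faces"] = (int) M.fa.size(), _["n_vertices"] = (int) M.vx.size());

  if (return_mesh) {
    size_t nv = M.vx.size(), nf = M.fa.size();
    NumericMatrix V((int) nv, 3);
    IntegerMatrix F((int) nf, 3);
    for (size_t v = 0; v < nv; ++v) {
      V(v, 0) = M.vx[v]; V(v, 1) = M.vy[v]; V(v, 2) = M.vz[v];
    }
    for (size_t q = 0; q < nf; ++q) {
      F(q, 0) = M.fa[q] + 1; F(q, 1) = M.fb[q] + 1; F(q, 2) = M.fc[q] + 1;
    }
    out["vertices"] = V;
    out["faces"] = F;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_isosurface_stats(NumericVector values, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericVector levels,
                               Nullable<IntegerVector> domain) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector keep;
  const int* dom = domain_ptr(domain, keep);
  int nl = levels.size();

  NumericVector area(nl), vol(nl);
  IntegerVector open_edges(nl), ncomp(nl), nfaces(nl);
  double cx = origin[0] + 0.5 * (nx - 1) * spacing[0];
  double cy = origin[1] + 0.5 * (ny - 1) * spacing[1];
  double cz = origin[2] + 0.5 * (nz - 1) * spacing[2];

  for (int l = 0; l < nl; ++l) {
    IsoMesh M;
    build_isosurface(REAL(values), nx, ny, nz,
                     spacing[0], spacing[1], spacing[2],
                     origin[0], origin[1], origin[2], levels[l], dom, M);
    double a, v; int oe, nc;
    mesh_stats(M, cx, cy, cz, a, v, oe, nc);
    area[l] = a; vol[l] = v;
    open_edges[l] = oe; ncomp[l] = nc; nfaces[l] = (int) M.fa.size();
  }
  return DataFrame::create(
    _["level"] = levels, _["area"] = area, _["volume"] = vol,
    _["open_edges"] = open_edges, _["n_components"] = ncomp,
    _["n_faces"] = nfaces);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), separable
// over the three axes with anisotropic voxel spacing. Distances are measured
// between voxel centres in mm.
// ---------------------------------------------------------------------------

static const double DT_INF = 1e30;

static void dt1d(const double* f, double* d, int n, double s,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sint <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t) nx * ny * nz;
  NumericVector out(n);
  double* D = REAL(out);
  const int* m = LOGICAL(mask);
  for (size_t i = 0; i < n; ++i) D[i] = m[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t) nx * (j + (size_t) ny * k);
      dt1d(D + base, d.data(), nx, spacing[0], v.data(), z.data());
      std::copy(d.begin(), d.begin() + nx, D + base);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t) i + (size_t) nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (size_t) nx * j];
      dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; ++j) D[base + (size_t) nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t) i + (size_t) nx * j;
      size_t str = (size_t) nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = D[base + str * k];
      dt1d(f.data(), d.data(), nz, spacing[2], v.data(), z.data());
      for (int k = 0; k < nz; ++k) D[base + str * k] = d[k];
    }

  for (size_t i = 0; i < n; ++i)
    D[i] = (D[i] >= DT_INF) ? R_PosInf : std::sqrt(D[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Signed distance from arbitrary points to a star-shaped surface
// R(u) = r0 * (1 + sum_j amp_j * exp(-|u - c_j|^2 / (2 sigma_j^2))),
// u on the unit sphere. The nearest surface point is located by discrete
// descent on a precomputed (theta, phi) sample grid followed by local grid
// refinement, which is robust for star-shaped surfaces with bounded
// perturbation. Negative inside, positive outside.
// ---------------------------------------------------------------------------

struct StarShape {
  int m;
  const double* cx; const double* cy; const double* cz;
  const double* amp; std::vector<double> inv2s2;
  double r0;

  double radius(double ux, double uy, double uz) const {
    double p = 1.0;
    for (int j = 0; j < m; ++j) {
      double dx = ux - cx[j], dy = uy - cy[j], dz = uz - cz[j];
      p += amp[j] * std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2[j]);
    }
    return r0 * p;
  }

  void surf(double th, double ph, double* out) const {
    double st = std::sin(th), ct = std::cos(th);
    double ux = st * std::cos(ph), uy = st * std::sin(ph), uz = ct;
    double R = radius(ux, uy, uz);
    out[0] = R * ux; out[1] = R * uy; out[2] = R * uz;
  }
};

static inline double dist2(const double* a, double bx, double by, double bz) {
  double dx = a[0] - bx, dy = a[1] - by, dz = a[2] - bz;
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_star_signed_distance(NumericMatrix pts, NumericMatrix centers,
                                       NumericVector amp, NumericVector sigma,
                                       double r0, int ntheta, int nrefine) {
  int npt = pts.nrow(), m = centers.nrow();
  StarShape S;
  S.m = m; S.r0 = r0;
  std::vector<double> ccx(m), ccy(m), ccz(m), aa(m);
  S.inv2s2.resize(m);
  for (int j = 0; j < m; ++j) {
    ccx[j] = centers(j, 0); ccy[j] = centers(j, 1); ccz[j] = centers(j, 2);
    aa[j] = amp[j];
    S.inv2s2[j] = 0.5 / (sigma[j] * sigma[j]);
  }
  S.cx = ccx.data(); S.cy = ccy.data(); S.cz = ccz.data(); S.amp = aa.data();

  int nth = ntheta, nph = 2 * ntheta;
  double dth = M_PI / nth, dph = 2.0 * M_PI / nph;
  // sample thetas at cell centres so the poles are handled by refinement
  std::vector<double> G((size_t) nth * nph * 3);
  for (int it = 0; it < nth; ++it) {
    double th = (it + 0.5) * dth;
    for (int ip = 0; ip < nph; ++ip)
      S.surf(th, ip * dph, &G[3 * ((size_t) it * nph + ip)]);
  }

  NumericVector out(npt);
  for (int q = 0; q < npt; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    double rho = std::sqrt(x * x + y * y + z * z);
    double th0, ph0;
    if (rho < 1e-12) { th0 = 0.5 * M_PI; ph0 = 0.0; }
    else {
      th0 = std::acos(std::max(-1.0, std::min(1.0, z / rho)));
      ph0 = std::atan2(y, x);
      if (ph0 < 0) ph0 += 2.0 * M_PI;
    }
    int it = std::max(0, std::min(nth - 1, (int) std::floor(th0 / dth)));
    int ip = ((int) std::floor(ph0 / dph)) % nph;

    double best = dist2(&G[3 * ((size_t) it * nph + ip)], x, y, z);
    // steepest-descent walk on the sample grid
    for (int iter = 0; iter < 4 * nth; ++iter) {
      int bi = it, bp = ip;
      double bd = best;
      for (int di = -1; di <= 1; ++di) {
        for (int dp = -1; dp <= 1; ++dp) {
          if (!di && !dp) continue;
          int ti = it + di;
          int tp = (ip + dp + nph) % nph;
          if (ti < 0 || ti >= nth) {
            // step across the pole
            ti = (ti < 0) ? 0 : nth - 1;
            tp = (tp + nph / 2) % nph;
          }
          double dd = dist2(&G[3 * ((size_t) ti * nph + tp)], x, y, z);
          if (dd < bd) { bd = dd; bi = ti; bp = tp; }
        }
      }
      if (bd >= best) break;
      best = bd; it = bi; ip = bp;
    }

    // continuous local refinement around the best sample
    double thc = (it + 0.5) * dth, phc = ip * dph;
    double hth = dth, hph = dph, p3[3];
    for (int r = 0; r < nrefine; ++r) {
      double bth = thc, bph = phc;
      for (int di = -1; di <= 1; ++di) {
        for (int dp = -1; dp <= 1; ++dp) {
          if (!di && !dp) continue;
          double tt = thc + di * hth;
          double pp = phc + dp * hph;
          if (tt < 0.0) { tt = -tt; pp += M_PI; }
          if (tt > M_PI) { tt = 2.0 * M_PI - tt; pp += M_PI; }
          S.surf(tt, pp, p3);
          double dd = dist2(p3, x, y, z);
          if (dd < best) { best = dd; bth = tt; bph = pp; }
        }
      }
      thc = bth; phc = bph;
      hth *= 0.5; hph *= 0.5;
    }

    double dist = std::sqrt(best);
    double inside;
    if (rho < 1e-12) inside = 1.0;
    else inside = (rho < S.radius(x / rho, y / rho, z / rho)) ? 1.0 : -1.0;
    out[q] = (inside > 0) ? -dist : dist;
  }
  return out;
}
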