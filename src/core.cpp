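#include <Rcpp.h>
using namespace Rcpp;

// Exact nearest-neighbour search and hexahedral point location.
//
// Both routines are deterministic and, for the NN search, the grid-indexed
// path accumulates squared distances with the same arithmetic as the brute
// force path, so ties resolve identically (smallest reference index).

static inline double sqdist(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

static void nn_brute_range(const double* q, const double* ref, int nr,
                           double& best, int& bidx) {
  for (int j = 0; j < nr; ++j) {
    double d2 = sqdist(q, ref + 3 * j);
    if (d2 < best) { best = d2; bidx = j; }
  }
}

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("reference point set is empty");
  if (query.ncol() != 3 || ref.ncol() != 3) stop("points must be n x 3");

  // copy to row-major buffers for locality
  std::vector<double> Q(3 * (size_t)nq), R(3 * (size_t)nr);
  for (int i = 0; i < nq; ++i)
    for (int d = 0; d < 3; ++d) Q[3 * (size_t)i + d] = query(i, d);
  for (int j = 0; j < nr; ++j)
    for (int d = 0; d < 3; ++d) R[3 * (size_t)j + d] = ref(j, d);

  IntegerVector idx(nq);
  NumericVector dist(nq);

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int j = 0; j < nr; ++j)
    for (int d = 0; d < 3; ++d) {
      double v = R[3 * (size_t)j + d];
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  bool degen = false;
  for (int d = 0; d < 3; ++d) if (!(hi[d] > lo[d])) degen = true;

  if (nr <= 512 || degen) {
    for (int i = 0; i < nq; ++i) {
      double best = R_PosInf; int bidx = -1;
      nn_brute_range(&Q[3 * (size_t)i], R.data(), nr, best, bidx);
      idx[i] = bidx + 1; dist[i] = std::sqrt(best);
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
  }

  // uniform grid: ~2 reference points per cell
  int n[3]; double cs[3];
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= (hi[d] - lo[d]);
  double h = std::cbrt(vol * 2.0 / nr);
  for (int d = 0; d < 3; ++d) {
    n[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
    cs[d] = (hi[d] - lo[d]) / n[d];
  }
  double hmin = std::min(cs[0], std::min(cs[1], cs[2]));
  size_t ncell = (size_t)n[0] * n[1] * n[2];

  std::vector<int> count(ncell + 1, 0), cell_of(nr);
  for (int j = 0; j < nr; ++j) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      int k = (int)std::floor((R[3 * (size_t)j + d] - lo[d]) / cs[d]);
      c[d] = std::min(std::max(k, 0), n[d] - 1);
    }
    cell_of[j] = c[0] + n[0] * (c[1] + n[1] * c[2]);
    ++count[cell_of[j] + 1];
  }
  for (size_t c = 0; c < ncell; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(nr), cursor(count.begin(), count.end() - 1);
  for (int j = 0; j < nr; ++j) bucket[cursor[cell_of[j]]++] = j;

  for (int i = 0; i < nq; ++i) {
    const double* q = &Q[3 * (size_t)i];
    int ci[3];
    for (int d = 0; d < 3; ++d)
      ci[d] = (int)std::floor((q[d] - lo[d]) / cs[d]);
    int maxr = 0;
    for (int d = 0; d < 3; ++d) {
      maxr = std::max(maxr, std::max(ci[d], 0) + 1);
      maxr = std::max(maxr, (n[d] - 1 - std::min(ci[d], n[d] - 1)) + 1);
    }
    double best = R_PosInf; int bidx = -1;
    for (int r = 0; ; ++r) {
      if (bidx >= 0) {
        double bound = (double)(r - 1) * hmin;
        if (bound > 0 && bound * bound > best) break;
      }
      if (r > maxr + 1) break;
      for (int dz = -r; dz <= r; ++dz) {
        int z = ci[2] + dz;
        if (z < 0 || z >= n[2]) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int y = ci[1] + dy;
          if (y < 0 || y >= n[1]) continue;
          bool face_z = std::abs(dz) == r, face_y = std::abs(dy) == r;
          int xlo = -r, xhi = r, xstep = 1;
          if (face_z || face_y) { /* full row */ }
          else { xstep = 2 * r; if (xstep == 0) xstep = 1; }
          for (int dx = xlo; dx <= xhi; dx += xstep) {
            if (!face_z && !face_y && std::abs(dx) != r) continue;
            int x = ci[0] + dx;
            if (x < 0 || x >= n[0]) continue;
            size_t cell = (size_t)x + n[0] * ((size_t)y + (size_t)n[1] * z);
            for (int t = count[cell]; t < count[cell + 1]; ++t) {
              int j = bucket[t];
              double d2 = sqdist(q, &R[3 * (size_t)j]);
              if (d2 < best || (d2 == best && j < bidx)) { best = d2; bidx = j; }
            }
          }
        }
      }
    }
    idx[i] = bidx + 1; dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// trilinear shape functions, VTK hexahedron corner order:
// bottom (w=0): (0,0) (1,0) (1,1) (0,1); top (w=1): same cycle
static inline void shape_fun(double u, double v, double w, double* N) {
  double um = 1 - u, vm = 1 - v, wm = 1 - w;
  N[0] = um * vm * wm; N[1] = u * vm * wm; N[2] = u * v * wm; N[3] = um * v * wm;
  N[4] = um * vm * w;  N[5] = u * vm * w;  N[6] = u * v * w;  N[7] = um * v * w;
}

static inline void shape_grad(double u, double v, double w, double G[8][3]) {
  double um = 1 - u, vm = 1 - v, wm = 1 - w;
  G[0][0] = -vm * wm; G[0][1] = -um * wm; G[0][2] = -um * vm;
  G[1][0] =  vm * wm; G[1][1] = -u * wm;  G[1][2] = -u * vm;
  G[2][0] =  v * wm;  G[2][1] =  u * wm;  G[2][2] = -u * v;
  G[3][0] = -v * wm;  G[3][1] =  um * wm; G[3][2] = -um * v;
  G[4][0] = -vm * w;  G[4][1] = -um * w;  G[4][2] =  um * vm;
  G[5][0] =  vm * w;  G[5][1] = -u * w;   G[5][2] =  u * vm;
  G[6][0] =  v * w;   G[6][1] =  u * w;   G[6][2] =  u * v;
  G[7][0] = -v * w;   G[7][1] =  um * w;  G[7][2] =  um * v;
}

// Newton inversion of the trilinear map; returns true if p lies inside.
static bool invert_trilinear(const double C[8][3], const double* p,
                             double& u, double& v, double& w) {
  u = v = w = 0.5;
  double N[8], G[8][3];
  for (int it = 0; it < 25; ++it) {
    shape_fun(u, v, w, N);
    double F[3] = { -p[0], -p[1], -p[2] };
    for (int c = 0; c < 8; ++c)
      for (int d = 0; d < 3; ++d) F[d] += N[c] * C[c][d];
    shape_grad(u, v, w, G);
    double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int c = 0; c < 8; ++c)
      for (int d = 0; d < 3; ++d)
        for (int e = 0; e < 3; ++e) J[d][e] += C[c][d] * G[c][e];
    double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
               - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
               + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
    if (std::abs(det) < 1e-300) return false;
    // Cramer solve J * step = F
    double s[3];
    s[0] = (F[0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
          - J[0][1] * (F[1] * J[2][2] - J[1][2] * F[2])
          + J[0][2] * (F[1] * J[2][1] - J[1][1] * F[2])) / det;
    s[1] = (J[0][0] * (F[1] * J[2][2] - J[1][2] * F[2])
          - F[0] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
          + J[0][2] * (J[1][0] * F[2] - F[1] * J[2][0])) / det;
    s[2] = (J[0][0] * (J[1][1] * F[2] - F[1] * J[2][1])
          - J[0][1] * (J[1][0] * F[2] - F[1] * J[2][0])
          + F[0] * (J[1][0] * J[2][1] - J[1][1] * J[2][0])) / det;
    u -= s[0]; v -= s[1]; w -= s[2];
    if (std::abs(s[0]) < 1e-13 && std::abs(s[1]) < 1e-13 && std::abs(s[2]) < 1e-13)
      break;
    // walked far away: give up
    if (u < -2 || u > 3 || v < -2 || v > 3 || w < -2 || w > 3) return false;
  }
  shape_fun(u, v, w, N);
  double F[3] = { -p[0], -p[1], -p[2] };
  for (int c = 0; c < 8; ++c)
    for (int d = 0; d < 3; ++d) F[d] += N[c] * C[c][d];
  double res = std::abs(F[0]) + std::abs(F[1]) + std::abs(F[2]);
  const double tol = 1e-9;
  return res < 1e-6 &&
         u > -tol && u < 1 + tol && v > -tol && v < 1 + tol &&
         w > -tol && w < 1 + tol;
}

// Locate axis-aligned voxel centres inside hexahedral elements.
// Voxel centre (i,j,k), 0-based, sits at origin + (i,j,k)*spacing.
// A voxel claimed by several elements keeps the smallest element index.
// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix nodes, IntegerMatrix elements,
                   NumericVector origin, NumericVector spacing,
                   IntegerVector dims) {
  const int ne = elements.nrow();
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const size_t nvox = (size_t)dx * dy * dz;
  IntegerVector elem(nvox, 0);
  NumericVector U(nvox), V(nvox), W(nvox);

  for (int e = 0; e < ne; ++e) {
    double C[8][3];
    double blo[3] = { R_PosInf, R_PosInf, R_PosInf };
    double bhi[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int c = 0; c < 8; ++c) {
      int nd = elements(e, c) - 1;
      for (int d = 0; d < 3; ++d) {
        C[c][d] = nodes(nd, d);
        if (C[c][d] < blo[d]) blo[d] = C[c][d];
        if (C[c][d] > bhi[d]) bhi[d] = C[c][d];
      }
    }
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = std::max(0, (int)std::ceil((blo[d] - origin[d]) / spacing[d] - 1e-9));
      i1[d] = std::min(dims[d] - 1,
                       (int)std::floor((bhi[d] - origin[d]) / spacing[d] + 1e-9));
    }
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i) {
          size_t lin = (size_t)i + dx * ((size_t)j + (size_t)dy * k);
          if (elem[lin] != 0) continue;
          double p[3] = { origin[0] + i * spacing[0],
                          origin[1] + j * spacing[1],
                          origin[2] + k * spacing[2] };
          double u, v, w;
          if (invert_trilinear(C, p, u, v, w)) {
            elem[lin] = e + 1;
            U[lin] = std::min(std::max(u, 0.0), 1.0);
            V[lin] = std::min(std::max(v, 0.0), 1.0);
            W[lin] = std::min(std::max(w, 0.0), 1.0);
          }
        }
  }
  return List::create(_["element"] = elem, _["u"] = U, _["v"] = V, _["w"] = W);
}
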