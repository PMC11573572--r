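#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image displacement along one axis.
static inline double mi1(double d, double L, bool periodic) {
  if (!periodic) return d;
  d -= L * std::round(d / L);
  return d;
}

static inline double mi_dist2(double dx, double dy, double dz,
                              double lx, double ly, double lz,
                              bool px, bool py, bool pz) {
  dx = mi1(dx, lx, px);
  dy = mi1(dy, ly, py);
  dz = mi1(dz, lz, pz);
  return dx * dx + dy * dy + dz * dz;
}

struct CellGrid {
  int ncx, ncy, ncz;
  double lx, ly, lz;
  bool px, py, pz;
  std::vector< std::vector<int> > cells;

  CellGrid(double lx_, double ly_, double lz_, bool px_, bool py_, bool pz_,
           double cutoff)
      : lx(lx_), ly(ly_), lz(lz_), px(px_), py(py_), pz(pz_) {
    ncx = std::max(1, (int)std::floor(lx / cutoff));
    ncy = std::max(1, (int)std::floor(ly / cutoff));
    ncz = std::max(1, (int)std::floor(lz / cutoff));
    // cap grid size for memory sanity
    ncx = std::min(ncx, 128); ncy = std::min(ncy, 128); ncz = std::min(ncz, 128);
    cells.resize((size_t)ncx * ncy * ncz);
  }
  inline int cidx(double x, double y, double z) const {
    int ix = (int)std::floor(x / lx * ncx);
    int iy = (int)std::floor(y / ly * ncy);
    int iz = (int)std::floor(z / lz * ncz);
    ix = std::min(std::max(ix, 0), ncx - 1);
    iy = std::min(std::max(iy, 0), ncy - 1);
    iz = std::min(std::max(iz, 0), ncz - 1);
    return (iz * ncy + iy) * ncx + ix;
  }
  inline void insert(int id, double x, double y, double z) {
    cells[cidx(x, y, z)].push_back(id);
  }
  // collect ids in the 27-neighborhood of the cell containing (x,y,z)
  void neighbors(double x, double y, double z, std::vector<int> &out) const {
    out.clear();
    int ix = (int)std::floor(x / lx * ncx);
    int iy = (int)std::floor(y / ly * ncy);
    int iz = (int)std::floor(z / lz * ncz);
    ix = std::min(std::max(ix, 0), ncx - 1);
    iy = std::min(std::max(iy, 0), ncy - 1);
    iz = std::min(std::max(iz, 0), ncz - 1);
    for (int dz = -1; dz <= 1; ++dz) {
      int jz = iz + dz;
      if (pz) jz = (jz + ncz) % ncz; else if (jz < 0 || jz >= ncz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = iy + dy;
        if (py) jy = (jy + ncy) % ncy; else if (jy < 0 || jy >= ncy) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx;
          if (px) jx = (jx + ncx) % ncx; else if (jx < 0 || jx >= ncx) continue;
          const std::vector<int> &c = cells[(size_t)(jz * ncy + jy) * ncx + jx];
          out.insert(out.end(), c.begin(), c.end());
        }
      }
    }
  }
};

// All pairs (i < j) within `cutoff` (minimum image) in one point set.
// Returns a data.frame-able list: i, j (1-based), dist.
// Cell-list search; small grids (< 3 cells per periodic axis) fall back to
// an all-pairs scan so the 27-neighborhood never double counts.
// [[Rcpp::export]]
List cpp_pairs_within(NumericVector x, NumericVector y, NumericVector z,
                      double lx, double ly, double lz,
                      bool px, bool py, bool pz, double cutoff) {
  int n = x.size();
  std::vector<int> oi, oj;
  std::vector<double> od;
  double c2 = cutoff * cutoff;
  bool small_grid =
      (px && lx / cutoff < 3) || (py && ly / cutoff < 3) || (pz && lz / cutoff < 3);
  if (n <= 64 || small_grid) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d2 = mi_dist2(x[i] - x[j], y[i] - y[j], z[i] - z[j],
                             lx, ly, lz, px, py, pz);
        if (d2 <= c2) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2)); }
      }
  } else {
    CellGrid g(lx, ly, lz, px, py, pz, cutoff);
    for (int i = 0; i < n; ++i) g.insert(i, x[i], y[i], z[i]);
    std::vector<int> nb;
    for (int i = 0; i < n; ++i) {
      g.neighbors(x[i], y[i], z[i], nb);
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        if (j <= i) continue;
        double d2 = mi_dist2(x[i] - x[j], y[i] - y[j], z[i] - z[j],
                             lx, ly, lz, px, py, pz);
        if (d2 <= c2) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2)); }
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["dist"] = wrap(od));
}

// All pairs (a in A, b in B) within cutoff (minimum image). 1-based indices.
// [[Rcpp::export]]
List cpp_pairs_between(NumericVector ax, NumericVector ay, NumericVector az,
                       NumericVector bx, NumericVector by, NumericVector bz,
                       double lx, double ly, double lz,
                       bool px, bool py, bool pz, double cutoff) {
  int na = ax.size(), nb = bx.size();
  std::vector<int> oi, oj;
  std::vector<double> od;
  double c2 = cutoff * cutoff;
  bool small_grid =
      (px && lx / cutoff < 3) || (py && ly / cutoff < 3) || (pz && lz / cutoff < 3);
  if ((double)na * nb <= 65536.0 || small_grid) {
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < nb; ++j) {
        double d2 = mi_dist2(ax[i] - bx[j], ay[i] - by[j], az[i] - bz[j],
                             lx, ly, lz, px, py, pz);
        if (d2 <= c2) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2)); }
      }
  } else {
    CellGrid g(lx, ly, lz, px, py, pz, cutoff);
    for (int j = 0; j < nb; ++j) g.insert(j, bx[j], by[j], bz[j]);
    std::vector<int> nbh;
    for (int i = 0; i < na; ++i) {
      g.neighbors(ax[i], ay[i], az[i], nbh);
      for (size_t k = 0; k < nbh.size(); ++k) {
        int j = nbh[k];
        double d2 = mi_dist2(ax[i] - bx[j], ay[i] - by[j], az[i] - bz[j],
                             lx, ly, lz, px, py, pz);
        if (d2 <= c2) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2)); }
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["dist"] = wrap(od));
}

// Index (1-based) of the nearest 2D site for each query point. Brute force;
// used by Monte-Carlo area estimation where site counts are small.
// [[Rcpp::export]]
IntegerVector cpp_nearest_site2d(NumericVector qx, NumericVector qy,
                                 NumericVector sx, NumericVector sy) {
  int nq = qx.size(), ns = sx.size();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < ns; ++j) {
      double dx = qx[i] - sx[j], dy = qy[i] - sy[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// Sequential random insertion of n points into [lo, hi)^3 with a minimum
// distance to both previously accepted points and `existing` atoms
// (minimum image in the full box). Deterministic for a given seed.
// Returns an n x 3 matrix, or fewer rows if placement stalls.
// [[Rcpp::export]]
NumericMatrix cpp_place_points(int n,
                               NumericVector lo, NumericVector hi,
                               double mindist,
                               NumericVector ex, NumericVector ey, NumericVector ez,
                               double lx, double ly, double lz,
                               bool px, bool py, bool pz,
                               int seed, int max_tries) {
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> ux(lo[0], hi[0]);
  std::uniform_real_distribution<double> uy(lo[1], hi[1]);
  std::uniform_real_distribution<double> uz(lo[2], hi[2]);
  double m2 = mindist * mindist;

  CellGrid g(lx, ly, lz, px, py, pz, std::max(mindist, 1.0));
  std::vector<double> axs, ays, azs;
  int nex = ex.size();
  for (int i = 0; i < nex; ++i) {
    axs.push_back(ex[i]); ays.push_back(ey[i]); azs.push_back(ez[i]);
    g.insert(i, ex[i], ey[i], ez[i]);
  }
  std::vector<double> outx, outy, outz;
  std::vector<int> nb;
  for (int k = 0; k < n; ++k) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      double cx = ux(rng), cy = uy(rng), cz = uz(rng);
      g.neighbors(cx, cy, cz, nb);
      bool ok = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        if (mi_dist2(cx - axs[j], cy - ays[j], cz - azs[j],
                     lx, ly, lz, px, py, pz) < m2) { ok = false; break; }
      }
      if (ok) {
        int id = (int)axs.size();
        axs.push_back(cx); ays.push_back(cy); azs.push_back(cz);
        g.insert(id, cx, cy, cz);
        outx.push_back(cx); outy.push_back(cy); outz.push_back(cz);
        placed = true;
        break;
      }
    }
    if (!placed) break;
  }
  int m = (int)outx.size();
  NumericMatrix res(m, 3);
  for (int i = 0; i < m; ++i) { res(i, 0) = outx[i]; res(i, 1) = outy[i]; res(i, 2) = outz[i]; }
  return res;
}
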