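#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Exact radiological path lengths of rays through a binary voxel grid
// (Amanatides & Woo incremental traversal after slab clipping). The grid is
// axis-aligned with lower corner `origin` and isotropic voxel edge `voxel`;
// `occ` is the occupancy array in R's native column-major layout with
// dimensions `dims` = (nx, ny, nz). Rays start at `source` with unit
// direction rows in `dirs`; only the forward half-line (t >= 0) is traced.
// [[Rcpp::export(name = ".ray_grid_paths")]]
NumericVector ray_grid_paths(LogicalVector occ, IntegerVector dims,
                             NumericVector origin, double voxel,
                             NumericVector source, NumericMatrix dirs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nray = dirs.nrow();
  NumericVector out(nray);
  const double bmin[3] = {origin[0], origin[1], origin[2]};
  const double bmax[3] = {origin[0] + nx * voxel, origin[1] + ny * voxel,
                          origin[2] + nz * voxel};
  const int nvox[3] = {nx, ny, nz};
  const double o[3] = {source[0], source[1], source[2]};

  for (int r = 0; r < nray; ++r) {
    const double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    double tmin = 0.0, tmax = R_PosInf;
    bool miss = false;
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(d[k]) < 1e-15) {
        if (o[k] <= bmin[k] || o[k] >= bmax[k]) { miss = true; break; }
      } else {
        double t1 = (bmin[k] - o[k]) / d[k];
        double t2 = (bmax[k] - o[k]) / d[k];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
        if (tmin >= tmax) { miss = true; break; }
      }
    }
    if (miss) { out[r] = 0.0; continue; }

    int idx[3], step[3];
    double tnext[3], tdelta[3];
    for (int k = 0; k < 3; ++k) {
      const double pk = o[k] + (tmin + 1e-9) * d[k];
      int i = (int)std::floor((pk - bmin[k]) / voxel);
      if (i < 0) i = 0;
      if (i >= nvox[k]) i = nvox[k] - 1;
      idx[k] = i;
      if (d[k] > 0) {
        step[k] = 1;
        tnext[k] = (bmin[k] + (i + 1) * voxel - o[k]) / d[k];
        tdelta[k] = voxel / d[k];
      } else if (d[k] < 0) {
        step[k] = -1;
        tnext[k] = (bmin[k] + i * voxel - o[k]) / d[k];
        tdelta[k] = -voxel / d[k];
      } else {
        step[k] = 0;
        tnext[k] = R_PosInf;
        tdelta[k] = R_PosInf;
      }
    }

    double acc = 0.0, t = tmin;
    while (t < tmax) {
      int k = 0;
      if (tnext[1] < tnext[k]) k = 1;
      if (tnext[2] < tnext[k]) k = 2;
      const double texit = tnext[k] < tmax ? tnext[k] : tmax;
      if (texit > t) {
        const int lin = idx[0] + nx * (idx[1] + ny * idx[2]);
        if (occ[lin]) acc += texit - t;
      }
      t = tnext[k];
      tnext[k] += tdelta[k];
      idx[k] += step[k];
      if (idx[k] < 0 || idx[k] >= nvox[k]) break;
    }
    out[r] = acc;
  }
  return out;
}
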