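#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rasterize the spiral cochlear duct into a label grid.
//
// The duct is swept along densely spaced centerline samples.  Each sample i
// carries an orthonormal frame (tangent T, lateral N, up B) and local
// cross-section geometry.  A voxel may be claimed by any sample whose
// perpendicular slab it falls into (|axial offset| <= slabHalf); among
// those, the sample whose section centroid is nearest wins (a Voronoi rule
// along the duct), which keeps the assignment single-valued where
// neighboring windings approach each other.
//
// Cross-section layout in local (u = p.N, v = p.B) coordinates, all in um:
// the organ-of-Corti ridge (label 6) is a disk sitting on the basilar
// membrane (centred slightly above the centerline, so the membrane sheet
// continues beneath it); scala tympani (2) is the ellipse below the basilar
// slab v in [-mem, 0); scala media (3) sits on v = 0; the Reissner slab is
// v in [2 bSM, 2 bSM + mem); scala vestibuli (4) above it.  Membranes and a
// limbus-like connector strip on the modiolar side share label 5 so the
// membrane system is one connected sheet.  Everything else inside the
// enveloping superellipse (exponent 4, which hugs the stacked sections)
// and its surrounding wall shell is bone/wall (1).
//
// geom columns: aST bST aSM bSM aSV bSV mem wall rOC aEnv bEnv vEnvC
// [[Rcpp::export]]
IntegerVector cpp_voxelize_tube(IntegerVector dims, double vox,
                                NumericMatrix P, NumericMatrix Tm,
                                NumericMatrix Nm, NumericMatrix Bm,
                                NumericMatrix geom, double slabHalf) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(nvox, 0);
  std::vector<float> bestW(nvox, 1e30f);
  const int M = P.nrow();

  for (int i = 0; i < M; ++i) {
    const double aST = geom(i, 0), bST = geom(i, 1), aSM = geom(i, 2),
                 bSM = geom(i, 3), aSV = geom(i, 4), bSV = geom(i, 5),
                 mem = geom(i, 6), wall = geom(i, 7), rOC = geom(i, 8),
                 aEnv = geom(i, 9), bEnv = geom(i, 10), vEnvC = geom(i, 11);
    const double aOut = aEnv + wall, bOut = bEnv + wall;
    const double Cx = P(i, 0), Cy = P(i, 1), Cz = P(i, 2);
    const double Tx = Tm(i, 0), Ty = Tm(i, 1), Tz = Tm(i, 2);
    const double Nx_ = Nm(i, 0), Ny_ = Nm(i, 1), Nz_ = Nm(i, 2);
    const double Bx = Bm(i, 0), By = Bm(i, 1), Bz = Bm(i, 2);
    // extent of the section in the B (up) direction, relative to v = 0
    const double vLo = vEnvC - bOut, vHi = vEnvC + bOut;
    const double bExt = std::max(std::fabs(vLo), std::fabs(vHi));
    // world-axis half extents of the slab bounding box
    double half[3];
    const double Nv[3] = {Nx_, Ny_, Nz_}, Bv[3] = {Bx, By, Bz},
                 Tv[3] = {Tx, Ty, Tz};
    for (int ax = 0; ax < 3; ++ax)
      half[ax] = aOut * std::fabs(Nv[ax]) + bExt * std::fabs(Bv[ax]) +
                 slabHalf * std::fabs(Tv[ax]) + vox;
    const double Cc[3] = {Cx, Cy, Cz};
    int lo[3], hi[3], nd[3] = {nx, ny, nz};
    bool empty = false;
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = std::max(0, static_cast<int>(std::floor((Cc[ax] - half[ax]) / vox - 0.5)));
      hi[ax] = std::min(nd[ax] - 1, static_cast<int>(std::ceil((Cc[ax] + half[ax]) / vox - 0.5)));
      if (lo[ax] > hi[ax]) empty = true;
    }
    if (empty) continue;

    for (int z = lo[2]; z <= hi[2]; ++z) {
      const double pz = (z + 0.5) * vox - Cz;
      for (int y = lo[1]; y <= hi[1]; ++y) {
        const double py = (y + 0.5) * vox - Cy;
        const double wyz = py * Ty + pz * Tz;
        const double uyz = py * Ny_ + pz * Nz_;
        const double vyz = py * By + pz * Bz;
        R_xlen_t base = static_cast<R_xlen_t>(nx) * (y + static_cast<R_xlen_t>(ny) * z);
        for (int x = lo[0]; x <= hi[0]; ++x) {
          const double px = (x + 0.5) * vox - Cx;
          const double w = px * Tx + wyz;
          if (std::fabs(w) > slabHalf) continue;
          const R_xlen_t idx = base + x;
          const double u = px * Nx_ + uyz;
          const double v = px * Bx + vyz;
          // distance to this sample's section centroid decides ownership
          const double dv = v - vEnvC;
          const float d2 = static_cast<float>(w * w + u * u + dv * dv);
          if (d2 >= bestW[idx]) continue;
          int code = 0;
          // ridge disk center: high enough that the bottom half of the
          // basilar membrane slab stays membrane underneath the ridge
          const double vOC = rOC - mem / 2.0;
          const double e2u = (u / aEnv) * (u / aEnv),
                       e2v = (dv / bEnv) * (dv / bEnv);
          const bool inEnv = e2u * e2u + e2v * e2v <= 1.0;
          if (u * u + (v - vOC) * (v - vOC) <= rOC * rOC) {
            code = 6;
          } else {
            const double vST = -mem - bST, vSM = bSM,
                         vSV = 2.0 * bSM + mem + bSV;
            double du, dv;
            du = u / aST; dv = (v - vST) / bST;
            if (du * du + dv * dv <= 1.0) code = 2;
            else {
              du = u / aSM; dv = (v - vSM) / bSM;
              if (du * du + dv * dv <= 1.0) code = 3;
              else {
                du = u / aSV; dv = (v - vSV) / bSV;
                if (du * du + dv * dv <= 1.0) code = 4;
                else if (inEnv && ((v >= -mem && v < 0.0) ||
                                   (v >= 2.0 * bSM && v < 2.0 * bSM + mem)))
                  code = 5;                     // membrane slabs
                else if (inEnv && u >= -aSM - mem && u < 0.0 &&
                         v >= 0.0 && v < 2.0 * bSM)
                  code = 5;                     // limbus-side connector wedge
                else if (inEnv) code = 1;       // interior filler
                else {
                  const double o2u = (u / aOut) * (u / aOut),
                               o2v = (dv / bOut) * (dv / bOut);
                  if (o2u * o2u + o2v * o2v <= 1.0) code = 1;  // wall shell
                }
              }
            }
          }
          bestW[idx] = d2;
          lab[idx] = code;
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
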