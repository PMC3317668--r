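#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projector for a vertical rotation axis.
//
// The volume is passed z-fastest (dim = nz, nx, ny) so that the innermost
// accumulation over detector rows is contiguous.  For each angle theta the
// ray through detector column u runs along (-sin, cos) in the xy-plane;
// in-plane bilinear weights are shared by all z (detector rows).
//
// Returns line integrals in units of (attenuation unit) * vox_scale, laid
// out as (nz, nCols, nAngles).
// [[Rcpp::export]]
NumericVector cpp_project_volume(NumericVector volZfast,
                                 int nx, int ny, int nz,
                                 NumericVector anglesRad,
                                 int nCols, double axisOffsetPx,
                                 double stepVox, double rMaxVox,
                                 double voxScale) {
  const int nA = anglesRad.size();
  NumericVector out(static_cast<R_xlen_t>(nz) * nCols * nA);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (nCols - 1) / 2.0;
  const double *vol = volZfast.begin();
  std::vector<double> acc(nz);

  for (int a = 0; a < nA; ++a) {
    const double ct = std::cos(anglesRad[a]), st = std::sin(anglesRad[a]);
    for (int j = 0; j < nCols; ++j) {
      const double u = j - cdet - axisOffsetPx;
      double *dst = out.begin() + (static_cast<R_xlen_t>(a) * nCols + j) * nz;
      if (std::fabs(u) > rMaxVox) continue;
      const double tmax = std::sqrt(rMaxVox * rMaxVox - u * u);
      std::fill(acc.begin(), acc.end(), 0.0);
      for (double t = -tmax; t <= tmax; t += stepVox) {
        const double x = cx + u * ct - t * st;
        const double y = cy + u * st + t * ct;
        const int ix = static_cast<int>(std::floor(x));
        const int iy = static_cast<int>(std::floor(y));
        if (ix < 0 || ix >= nx - 1 || iy < 0 || iy >= ny - 1) continue;
        const double fx = x - ix, fy = y - iy;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy,       w11 = fx * fy;
        const double *c00 = vol + (static_cast<R_xlen_t>(iy) * nx + ix) * nz;
        const double *c10 = c00 + nz;
        const double *c01 = vol + (static_cast<R_xlen_t>(iy + 1) * nx + ix) * nz;
        const double *c11 = c01 + nz;
        for (int z = 0; z < nz; ++z)
          acc[z] += w00 * c00[z] + w10 * c10[z] + w01 * c01[z] + w11 * c11[z];
      }
      const double s = stepVox * voxScale;
      for (int z = 0; z < nz; ++z) dst[z] = acc[z] * s;
    }
  }
  out.attr("dim") = IntegerVector::create(nz, nCols, nA);
  return out;
}

// Backprojection of ramp-filtered projections (one slice).
// filt is nAngles x nDet; output is nDet x nDet, rotation axis at the
// detector/image center.  Linear interpolation along the detector.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filt, NumericVector anglesRad) {
  const int nA = filt.nrow(), nDet = filt.ncol();
  NumericMatrix out(nDet, nDet);
  const double c = (nDet - 1) / 2.0;
  for (int a = 0; a < nA; ++a) {
    const double ct = std::cos(anglesRad[a]), st = std::sin(anglesRad[a]);
    const NumericMatrix::Row row = filt(a, _);
    for (int iy = 0; iy < nDet; ++iy) {
      const double ys = (iy - c) * st + c;
      for (int ix = 0; ix < nDet; ++ix) {
        const double tp = (ix - c) * ct + ys;
        const int i0 = static_cast<int>(std::floor(tp));
        if (i0 < 0 || i0 >= nDet - 1) continue;
        const double f = tp - i0;
        out(ix, iy) += (1 - f) * row[i0] + f * row[i0 + 1];
      }
    }
  }
  return out;
}
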