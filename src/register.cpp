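#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear resampling of `img` under a rigid transform, into the fixed frame.
// The transform maps moving coordinates to fixed coordinates:
//   fixed = R(theta) * (moving - c) + c + t          (units: voxels)
// so each fixed-frame pixel samples the moving image at the inverse location.
// Out-of-field samples are zero-filled and flagged invalid in `mask`.
// [[Rcpp::export]]
List cpp_resample_rigid(NumericMatrix img, double dy, double dx, double theta,
                        double cy, double cx) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  LogicalMatrix mask(nr, nc);
  double ct = std::cos(theta), st = std::sin(theta);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      // inverse map: moving = R(-theta) * (fixed - c - t) + c
      double py = (double)i - cy - dy;
      double px = (double)j - cx - dx;
      double my = ct * py + st * px + cy;
      double mx = -st * py + ct * px + cx;
      int i0 = (int)std::floor(my), j0 = (int)std::floor(mx);
      if (i0 < 0 || j0 < 0 || i0 + 1 >= nr || j0 + 1 >= nc) {
        out(i, j) = 0.0;
        mask(i, j) = false;
        continue;
      }
      double fy = my - i0, fx = mx - j0;
      double v = (1 - fy) * (1 - fx) * img(i0, j0) +
                 (1 - fy) * fx * img(i0, j0 + 1) +
                 fy * (1 - fx) * img(i0 + 1, j0) +
                 fy * fx * img(i0 + 1, j0 + 1);
      out(i, j) = v;
      mask(i, j) = true;
    }
  }
  return List::create(_["values"] = out, _["mask"] = mask);
}

// Shannon mutual information (nats) between two images over a validity mask,
// from a joint histogram with `nbins` equal-width bins per marginal.
// [[Rcpp::export]]
double cpp_mutual_information(NumericMatrix a, NumericMatrix b,
                              LogicalMatrix mask, int nbins) {
  int n = a.nrow() * a.ncol();
  double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
  int m = 0;
  for (int k = 0; k < n; ++k) {
    if (!mask[k]) continue;
    ++m;
    amin = std::min(amin, a[k]); amax = std::max(amax, a[k]);
    bmin = std::min(bmin, b[k]); bmax = std::max(bmax, b[k]);
  }
  if (m < 2 || amax <= amin || bmax <= bmin) return 0.0;
  std::vector<double> joint(nbins * nbins, 0.0), pa(nbins, 0.0), pb(nbins, 0.0);
  double ascale = nbins / (amax - amin) * (1.0 - 1e-12);
  double bscale = nbins / (bmax - bmin) * (1.0 - 1e-12);
  for (int k = 0; k < n; ++k) {
    if (!mask[k]) continue;
    int ia = (int)((a[k] - amin) * ascale);
    int ib = (int)((b[k] - bmin) * bscale);
    joint[ia * nbins + ib] += 1.0;
  }
  double inv = 1.0 / m, mi = 0.0;
  for (int ia = 0; ia < nbins; ++ia)
    for (int ib = 0; ib < nbins; ++ib) {
      double p = joint[ia * nbins + ib] * inv;
      pa[ia] += p; pb[ib] += p;
    }
  for (int ia = 0; ia < nbins; ++ia)
    for (int ib = 0; ib < nbins; ++ib) {
      double p = joint[ia * nbins + ib] * inv;
      if (p > 0) mi += p * std::log(p / (pa[ia] * pb[ib]));
    }
  return mi;
}

// Pearson correlation over a validity mask; NA if < 2 pixels or zero variance.
// [[Rcpp::export]]
double cpp_masked_pearson(NumericMatrix a, NumericMatrix b, LogicalMatrix mask) {
  int n = a.nrow() * a.ncol(), m = 0;
  double sa = 0, sb = 0;
  for (int k = 0; k < n; ++k)
    if (mask[k]) { sa += a[k]; sb += b[k]; ++m; }
  if (m < 2) return NA_REAL;
  double ma = sa / m, mb = sb / m, saa = 0, sbb = 0, sab = 0;
  for (int k = 0; k < n; ++k) {
    if (!mask[k]) continue;
    double da = a[k] - ma, db = b[k] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}
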