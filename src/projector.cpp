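#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Parallel-beam voxel/ray geometry.
//
// A volume is an R array dim = (n1, n2, n3): n1 axial slices stacked along
// the rotation axis, each in-plane slice being an n2 x n3 image (rows y,
// columns x). A projection stack is an R array dim = (m1, m2, s): m1 = n1
// axial detector rows, m2 = n3 detector columns, s angles.
//
// The ray for detector column t at angle theta samples the in-plane slice
// at unit steps along the ray direction; sample (t, step) sits at
//   x = cx + tp*cos - sp*sin,  y = cy + tp*sin + sp*cos
// with tp = t - ct, sp = step - cs, rotation centre at the grid centre.
// At theta = 0 this reduces to summing each in-plane column, so detector
// column index == in-plane column index (the transverse axis).
//
// Bilinear interpolation weights are computed once per (angle, t, step)
// and reused across all axial slices (the axial rows are decoupled), which
// makes the inner loop a unit-stride saxpy over the axial index.

// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  NumericVector angles_rad) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int ns = angles_rad.size();
  const int m2 = n3;           // detector columns = in-plane columns
  const int nstep = n2;        // integration steps along the ray
  const double cy = 0.5 * (n2 - 1), cx = 0.5 * (n3 - 1);
  const double ct = 0.5 * (m2 - 1), cs = 0.5 * (nstep - 1);

  NumericVector out(static_cast<R_xlen_t>(n1) * m2 * ns);
  const double *v = vol.begin();
  double *o = out.begin();

  for (int is = 0; is < ns; ++is) {
    const double c = std::cos(angles_rad[is]), s = std::sin(angles_rad[is]);
    double *oang = o + static_cast<R_xlen_t>(is) * n1 * m2;
    for (int t = 0; t < m2; ++t) {
      const double tp = t - ct;
      double *ocol = oang + static_cast<R_xlen_t>(t) * n1;
      for (int st = 0; st < nstep; ++st) {
        const double sp = st - cs;
        const double x = cx + tp * c - sp * s;
        const double y = cy + tp * s + sp * c;
        const int x0 = static_cast<int>(std::floor(x));
        const int y0 = static_cast<int>(std::floor(y));
        if (x0 < -1 || x0 > n3 - 1 || y0 < -1 || y0 > n2 - 1) continue;
        const double fx = x - x0, fy = y - y0;
        const double w00 = (1 - fx) * (1 - fy), w01 = fx * (1 - fy);
        const double w10 = (1 - fx) * fy,       w11 = fx * fy;
        const bool okx0 = x0 >= 0, okx1 = x0 + 1 <= n3 - 1;
        const bool oky0 = y0 >= 0, oky1 = y0 + 1 <= n2 - 1;
        // vol index: a + n1*(y + n2*x)
        if (okx0 && oky0 && w00 != 0) {
          const double *p = v + static_cast<R_xlen_t>(n1) * (y0 + static_cast<R_xlen_t>(n2) * x0);
          for (int a = 0; a < n1; ++a) ocol[a] += w00 * p[a];
        }
        if (okx1 && oky0 && w01 != 0) {
          const double *p = v + static_cast<R_xlen_t>(n1) * (y0 + static_cast<R_xlen_t>(n2) * (x0 + 1));
          for (int a = 0; a < n1; ++a) ocol[a] += w01 * p[a];
        }
        if (okx0 && oky1 && w10 != 0) {
          const double *p = v + static_cast<R_xlen_t>(n1) * ((y0 + 1) + static_cast<R_xlen_t>(n2) * x0);
          for (int a = 0; a < n1; ++a) ocol[a] += w10 * p[a];
        }
        if (okx1 && oky1 && w11 != 0) {
          const double *p = v + static_cast<R_xlen_t>(n1) * ((y0 + 1) + static_cast<R_xlen_t>(n2) * (x0 + 1));
          for (int a = 0; a < n1; ++a) ocol[a] += w11 * p[a];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n1, m2, ns);
  return out;
}

// Exact transpose of cpp_forward_project onto an (n1, n2, n3) grid.
// [[Rcpp::export(name = ".cpp_back_project")]]
NumericVector cpp_back_project(NumericVector proj, IntegerVector pdim,
                               NumericVector angles_rad, IntegerVector vdim) {
  const int m1 = pdim[0], m2 = pdim[1];
  const int ns = angles_rad.size();
  const int n1 = vdim[0], n2 = vdim[1], n3 = vdim[2];
  const int nstep = n2;
  const double cy = 0.5 * (n2 - 1), cx = 0.5 * (n3 - 1);
  const double ct = 0.5 * (m2 - 1), cs = 0.5 * (nstep - 1);

  NumericVector out(static_cast<R_xlen_t>(n1) * n2 * n3);
  double *v = out.begin();
  const double *p = proj.begin();

  for (int is = 0; is < ns; ++is) {
    const double c = std::cos(angles_rad[is]), s = std::sin(angles_rad[is]);
    const double *pang = p + static_cast<R_xlen_t>(is) * m1 * m2;
    for (int t = 0; t < m2; ++t) {
      const double tp = t - ct;
      const double *pcol = pang + static_cast<R_xlen_t>(t) * m1;
      for (int st = 0; st < nstep; ++st) {
        const double sp = st - cs;
        const double x = cx + tp * c - sp * s;
        const double y = cy + tp * s + sp * c;
        const int x0 = static_cast<int>(std::floor(x));
        const int y0 = static_cast<int>(std::floor(y));
        if (x0 < -1 || x0 > n3 - 1 || y0 < -1 || y0 > n2 - 1) continue;
        const double fx = x - x0, fy = y - y0;
        const double w00 = (1 - fx) * (1 - fy), w01 = fx * (1 - fy);
        const double w10 = (1 - fx) * fy,       w11 = fx * fy;
        const bool okx0 = x0 >= 0, okx1 = x0 + 1 <= n3 - 1;
        const bool oky0 = y0 >= 0, oky1 = y0 + 1 <= n2 - 1;
        if (okx0 && oky0 && w00 != 0) {
          double *q = v + static_cast<R_xlen_t>(n1) * (y0 + static_cast<R_xlen_t>(n2) * x0);
          for (int a = 0; a < n1; ++a) q[a] += w00 * pcol[a];
        }
        if (okx1 && oky0 && w01 != 0) {
          double *q = v + static_cast<R_xlen_t>(n1) * (y0 + static_cast<R_xlen_t>(n2) * (x0 + 1));
          for (int a = 0; a < n1; ++a) q[a] += w01 * pcol[a];
        }
        if (okx0 && oky1 && w10 != 0) {
          double *q = v + static_cast<R_xlen_t>(n1) * ((y0 + 1) + static_cast<R_xlen_t>(n2) * x0);
          for (int a = 0; a < n1; ++a) q[a] += w10 * pcol[a];
        }
        if (okx1 && oky1 && w11 != 0) {
          double *q = v + static_cast<R_xlen_t>(n1) * ((y0 + 1) + static_cast<R_xlen_t>(n2) * (x0 + 1));
          for (int a = 0; a < n1; ++a) q[a] += w11 * pcol[a];
        }
      }
    }
  }
  out.attr("dim") = vdim;
  return out;
}

// Real-space bilinear translation of one image by (dh, dv) pixels:
// out(r, c) = img(r - dv, c - dh); pixels sampled outside the frame take
// `fill`. dh moves content toward increasing column index, dv toward
// increasing row index.
// [[Rcpp::export(name = ".cpp_translate")]]
NumericMatrix cpp_translate(NumericMatrix img, double dh, double dv,
                            double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double x = c - dh;
    const int x0 = static_cast<int>(std::floor(x));
    const double fx = x - x0;
    const bool okx0 = x0 >= 0 && x0 <= nc - 1;
    const bool okx1 = x0 + 1 >= 0 && x0 + 1 <= nc - 1;
    for (int r = 0; r < nr; ++r) {
      const double y = r - dv;
      const int y0 = static_cast<int>(std::floor(y));
      const double fy = y - y0;
      const bool oky0 = y0 >= 0 && y0 <= nr - 1;
      const bool oky1 = y0 + 1 >= 0 && y0 + 1 <= nr - 1;
      const double v00 = (okx0 && oky0) ? img(y0, x0) : fill;
      const double v01 = (okx1 && oky0) ? img(y0, x0 + 1) : fill;
      const double v10 = (okx0 && oky1) ? img(y0 + 1, x0) : fill;
      const double v11 = (okx1 && oky1) ? img(y0 + 1, x0 + 1) : fill;
      out(r, c) = (1 - fx) * ((1 - fy) * v00 + fy * v10) +
                  fx * ((1 - fy) * v01 + fy * v11);
    }
  }
  return out;
}
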