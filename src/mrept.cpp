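#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 6-connected component labelling over masked voxels, where two adjacent
// voxels join the same component only if they share the same integer key
// (pass a constant key to label plain mask components).
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector key, LogicalVector mask,
                          IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  int cur = 0;
  for (int seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    const int k0 = key[seed];
    lab[seed] = ++cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      const int i = stack.back();
      stack.pop_back();
      const int z = i / (nx * ny), r = i % (nx * ny);
      const int y = r / nx, x = r % nx;
      for (int d = 0; d < 6; ++d) {
        const int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int j = xx + nx * (yy + ny * zz);
        if (mask[j] && !lab[j] && key[j] == k0) {
          lab[j] = cur;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Least-squares quadratic y ~ a + b t + c t^2 through m points (t integer
// sample offsets). Returns c, plus the Pearson correlation between fitted
// and observed values in *cor (1 when the observations are flat or the fit
// is exact). saturated is set when m equals the number of parameters so the
// fit carries no residual degrees of freedom.
static bool quad_fit(const double *t, const double *y, int m,
                     double *c_out, double *cor, bool *saturated) {
  if (m < 3) return false;
  double s0 = m, s1 = 0, s2 = 0, s3 = 0, s4 = 0, b0 = 0, b1 = 0, b2 = 0;
  for (int i = 0; i < m; ++i) {
    const double ti = t[i], t2 = ti * ti;
    s1 += ti; s2 += t2; s3 += t2 * ti; s4 += t2 * t2;
    b0 += y[i]; b1 += ti * y[i]; b2 += t2 * y[i];
  }
  // 3x3 symmetric system via Cramer's rule
  const double det = s0 * (s2 * s4 - s3 * s3) - s1 * (s1 * s4 - s3 * s2) +
                     s2 * (s1 * s3 - s2 * s2);
  if (std::fabs(det) < 1e-12) return false;
  const double a = (b0 * (s2 * s4 - s3 * s3) - s1 * (b1 * s4 - s3 * b2) +
                    s2 * (b1 * s3 - s2 * b2)) / det;
  const double b = (s0 * (b1 * s4 - b2 * s3) - b0 * (s1 * s4 - s3 * s2) +
                    s2 * (s1 * b2 - s2 * b1)) / det;
  const double c = (s0 * (s2 * b2 - s3 * b1) - s1 * (s1 * b2 - b1 * s2) +
                    b0 * (s1 * s3 - s2 * s2)) / det;
  // Pearson r between fitted and observed
  double my = b0 / m, mf = 0;
  std::vector<double> fit(m);
  for (int i = 0; i < m; ++i) {
    fit[i] = a + b * t[i] + c * t[i] * t[i];
    mf += fit[i];
  }
  mf /= m;
  double vy = 0, vf = 0, cv = 0, scale = 0;
  for (int i = 0; i < m; ++i) {
    const double dy = y[i] - my, df = fit[i] - mf;
    vy += dy * dy; vf += df * df; cv += dy * df;
    scale += y[i] * y[i];
  }
  const double eps = 1e-18 * (scale + 1e-30);
  double r;
  if (vy <= eps) {
    r = 1.0;                      // flat observations: constant fit is exact
  } else if (vf <= eps) {
    r = 0.0;                      // varying data, flat fit
  } else {
    r = cv / std::sqrt(vy * vf);
    // exact interpolation can round to slightly > 1
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
  }
  *c_out = c;
  *cor = r;
  *saturated = (m == 3);
  return true;
}

// Average parabolic-fit Laplacian with tissue-label and amplitude kernel
// restriction. For every masked voxel and every axis, up to `half_ext`
// neighbours per side are collected walking outward, stopping at the first
// voxel that leaves the mask, changes tissue label, or differs in magnitude
// from the target by more than amp_tol (fractional). Each side with at
// least min_pts + 1 samples (target included) gets a least-squares
// parabola; the axis second derivative is the mean of the available side
// curvatures; the Laplacian is the sum over axes. A voxel is valid when
// every axis produced at least one fit and the aggregate fit correlation
// reaches cor_thresh. aggregate: 0 = mean over fits with residual dof
// (saturated 3-point fits excluded; 1 if none informative), 1 = min.
// [[Rcpp::export]]
List parabolic_laplacian_cpp(NumericVector phase, IntegerVector labels,
                             NumericVector mag, LogicalVector mask,
                             IntegerVector dims, IntegerVector half_ext,
                             NumericVector h_m, double amp_tol, int min_pts,
                             double cor_thresh, int aggregate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int stride[3] = {1, nx, nx * ny};
  NumericVector lap(n, NA_REAL);
  LogicalVector valid(n, false);
  NumericVector meancor(n, NA_REAL);
  double tbuf[16], ybuf[16];

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        if (!mask[i]) continue;
        const int lab0 = labels[i];
        const double m0 = mag[i];
        const int pos[3] = {x, y, z};
        const int lim[3] = {nx, ny, nz};
        double lap_i = 0;
        bool all_axes = true;
        double cor_sum = 0, cor_min = 1.0;
        int cor_n = 0;
        for (int d = 0; d < 3 && all_axes; ++d) {
          double axis_sum = 0;
          int axis_n = 0;
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            int m = 1;
            tbuf[0] = 0; ybuf[0] = phase[i];
            for (int s = 1; s <= half_ext[d]; ++s) {
              const int p = pos[d] + sgn * s;
              if (p < 0 || p >= lim[d]) break;
              const int j = i + sgn * s * stride[d];
              if (!mask[j] || labels[j] != lab0) break;
              if (std::fabs(mag[j] - m0) > amp_tol * std::fabs(m0)) break;
              tbuf[m] = s; ybuf[m] = phase[j]; ++m;
            }
            if (m >= min_pts + 1) {
              double c, r;
              bool sat;
              if (quad_fit(tbuf, ybuf, m, &c, &r, &sat)) {
                axis_sum += 2.0 * c / (h_m[d] * h_m[d]);
                ++axis_n;
                if (!sat) { cor_sum += r; ++cor_n; }
                if (r < cor_min) cor_min = r;
              }
            }
          }
          if (axis_n == 0) all_axes = false;
          else lap_i += axis_sum / axis_n;
        }
        if (!all_axes) continue;
        const double agg = (aggregate == 1)
          ? cor_min
          : (cor_n > 0 ? cor_sum / cor_n : 1.0);
        lap[i] = lap_i;
        meancor[i] = agg;
        valid[i] = (agg >= cor_thresh);
      }

  lap.attr("dim") = dims;
  valid.attr("dim") = dims;
  meancor.attr("dim") = dims;
  return List::create(_["values"] = lap, _["valid"] = valid,
                      _["fit_cor"] = meancor);
}
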