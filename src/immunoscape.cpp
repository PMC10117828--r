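// Inner loops for geometry and registration. Plain Rcpp, no external libs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Even-odd point-in-polygon with boundary counted as inside.
// poly: n x 2 matrix (open ring, no duplicated closing vertex).
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector x, NumericVector y,
                                   NumericMatrix poly) {
  const int np = x.size(), nv = poly.nrow();
  LogicalVector out(np);
  const double eps = 1e-12;
  for (int k = 0; k < np; ++k) {
    double px = x[k], py = y[k];
    bool inside = false, on_edge = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1);
      double xj = poly(j, 0), yj = poly(j, 1);
      // boundary check: point within eps of segment (i,j)
      double dx = xj - xi, dy = yj - yi;
      double len2 = dx * dx + dy * dy;
      double t = len2 > 0 ? ((px - xi) * dx + (py - yi) * dy) / len2 : 0.0;
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      double ex = px - (xi + t * dx), ey = py - (yi + t * dy);
      if (ex * ex + ey * ey < eps) { on_edge = true; break; }
      if (((yi > py) != (yj > py)) &&
          (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[k] = on_edge || inside;
  }
  return out;
}

// Minimum distance from each point to a set of segments given as vertex
// list; closed = include last->first segment.
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline(NumericVector x, NumericVector y,
                                   NumericMatrix line, bool closed) {
  const int np = x.size(), nv = line.nrow();
  NumericVector out(np);
  for (int k = 0; k < np; ++k) {
    double px = x[k], py = y[k], best = R_PosInf;
    int nseg = closed ? nv : nv - 1;
    for (int i = 0; i < nseg; ++i) {
      int j = (i + 1) % nv;
      double ax = line(i, 0), ay = line(i, 1);
      double dx = line(j, 0) - ax, dy = line(j, 1) - ay;
      double len2 = dx * dx + dy * dy;
      if (len2 <= 0) continue;
      double t = ((px - ax) * dx + (py - ay) * dy) / len2;
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      double ex = px - (ax + t * dx), ey = py - (ay + t * dy);
      double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[k] = std::sqrt(best);
  }
  return out;
}

static NumericVector gauss_kernel(double sigma) {
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  NumericVector k(2 * h + 1);
  double s = 0;
  for (int i = -h; i <= h; ++i) {
    double v = std::exp(-0.5 * i * i / (sigma * sigma));
    k[i + h] = v; s += v;
  }
  for (int i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// Separable Gaussian blur with zero padding at the borders.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  NumericVector k = gauss_kernel(sigma);
  int h = (k.size() - 1) / 2;
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int t = -h; t <= h; ++t) {
        int ii = i + t;
        if (ii >= 0 && ii < nr) s += k[t + h] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double s = 0;
      for (int t = -h; t <= h; ++t) {
        int jj = j + t;
        if (jj >= 0 && jj < nc) s += k[t + h] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// One box-blur pass of odd width w along rows then cols, replicate-edge.
static void box_pass(std::vector<double> &v, std::vector<double> &tmp,
                     int nr, int nc, int h) {
  // rows (within each column)
  for (int j = 0; j < nc; ++j) {
    double *col = &v[(size_t)j * nr];
    double s = 0;
    for (int t = -h; t <= h; ++t) s += col[std::min(std::max(t, 0), nr - 1)];
    for (int i = 0; i < nr; ++i) {
      tmp[(size_t)j * nr + i] = s / (2 * h + 1);
      int add = std::min(i + h + 1, nr - 1), rem = std::max(i - h, 0);
      s += col[add] - col[rem];
    }
  }
  // cols (within each row)
  for (int i = 0; i < nr; ++i) {
    double s = 0;
    for (int t = -h; t <= h; ++t)
      s += tmp[(size_t)std::min(std::max(t, 0), nc - 1) * nr + i];
    for (int j = 0; j < nc; ++j) {
      v[(size_t)j * nr + i] = s / (2 * h + 1);
      int add = std::min(j + h + 1, nc - 1), rem = std::max(j - h, 0);
      s += tmp[(size_t)add * nr + i] - tmp[(size_t)rem * nr + i];
    }
  }
}

// Three iterated box blurs approximating a Gaussian of sd sigma.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_field(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  int nr = img.nrow(), nc = img.ncol();
  int h = std::max(1, (int)std::round(std::sqrt(sigma * sigma / 3.0 * 4.0 + 1.0) / 2.0));
  std::vector<double> v(img.begin(), img.end()), tmp(v.size());
  for (int k = 0; k < 3; ++k) box_pass(v, tmp, nr, nc, h);
  NumericMatrix out(nr, nc);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

static inline double bilinear(const NumericMatrix &img, double r, double c) {
  // clamp-to-edge sampling; (r, c) are 0-based fractional indices
  int nr = img.nrow(), nc = img.ncol();
  if (r < 0) r = 0; if (r > nr - 1) r = nr - 1;
  if (c < 0) c = 0; if (c > nc - 1) c = nc - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return img(r0, c0) * (1 - fr) * (1 - fc) + img(r1, c0) * fr * (1 - fc) +
         img(r0, c1) * (1 - fr) * fc + img(r1, c1) * fr * fc;
}

// Sample img at arbitrary fractional (row, col) positions.
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector row,
                                  NumericVector col) {
  int n = row.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bilinear(img, row[i], col[i]);
  return out;
}

// Rigid resample: out(r, c) = img(R_theta((r,c) + u - center) + center),
// theta in radians, u = (ur, uc) translation in the output frame.
// [[Rcpp::export]]
NumericMatrix cpp_rigid_resample(NumericMatrix img, double theta,
                                 double ur, double uc) {
  int nr = img.nrow(), nc = img.ncol();
  double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  double ct = std::cos(theta), st = std::sin(theta);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double dr = i + ur - cr, dc = j + uc - cc;
      double sr = ct * dr - st * dc + cr;
      double sc = st * dr + ct * dc + cc;
      out(i, j) = bilinear(img, sr, sc);
    }
  return out;
}

// Demons non-rigid registration: finds displacement u with
// moving(x + u(x)) ~= fixed(x). Displacements in pixels, diffusion-like
// regularization by Gaussian smoothing of the field each iteration.
// Returns best-so-far field and the MSE trace.
// [[Rcpp::export]]
List cpp_demons(NumericMatrix fixed_img, NumericMatrix moving_img,
                double sigma_field, int max_iter, double step,
                double tol, int patience) {
  int nr = fixed_img.nrow(), nc = fixed_img.ncol();
  NumericMatrix ur(nr, nc), uc(nr, nc);   // displacement rows/cols
  NumericMatrix best_ur(nr, nc), best_uc(nr, nc);
  // fixed-image gradient (central differences)
  NumericMatrix gr(nr, nc), gc(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      gr(i, j) = 0.5 * (fixed_img(std::min(i + 1, nr - 1), j) -
                        fixed_img(std::max(i - 1, 0), j));
      gc(i, j) = 0.5 * (fixed_img(i, std::min(j + 1, nc - 1)) -
                        fixed_img(i, std::max(j - 1, 0)));
    }
  std::vector<double> trace;
  double best_mse = R_PosInf;
  int bad = 0, n = nr * nc;
  for (int it = 0; it < max_iter; ++it) {
    double mse = 0;
    NumericMatrix vr(nr, nc), vc(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double w = bilinear(moving_img, i + ur(i, j), j + uc(i, j));
        double d = fixed_img(i, j) - w;
        mse += d * d;
        double g2 = gr(i, j) * gr(i, j) + gc(i, j) * gc(i, j);
        double denom = g2 + d * d + 1e-12;
        vr(i, j) = d * gr(i, j) / denom;
        vc(i, j) = d * gc(i, j) / denom;
      }
    mse /= n;
    trace.push_back(mse);
    if (mse < best_mse - tol * best_mse) {
      bad = 0;
    } else {
      if (++bad >= patience) break;
    }
    if (mse < best_mse) {
      best_mse = mse;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) { best_ur(i, j) = ur(i, j); best_uc(i, j) = uc(i, j); }
    }
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        ur(i, j) += step * vr(i, j);
        uc(i, j) += step * vc(i, j);
      }
    ur = cpp_smooth_field(ur, sigma_field);
    uc = cpp_smooth_field(uc, sigma_field);
  }
  // final evaluation of the last field
  double mse = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double w = bilinear(moving_img, i + ur(i, j), j + uc(i, j));
      double d = fixed_img(i, j) - w;
      mse += d * d;
    }
  mse /= n;
  trace.push_back(mse);
  if (mse < best_mse) {
    best_mse = mse;
    best_ur = ur; best_uc = uc;
  }
  return List::create(_["ur"] = best_ur, _["uc"] = best_uc,
                      _["mse"] = best_mse, _["trace"] = NumericVector(trace.begin(), trace.end()));
}
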