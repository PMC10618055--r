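#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Euclidean distance matrix for n x 2 positions.
// [[Rcpp::export]]
NumericMatrix cpp_dist_matrix(const NumericMatrix& pos) {
  int n = pos.nrow();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dd = std::sqrt(dx * dx + dy * dy);
      d(i, j) = dd;
      d(j, i) = dd;
    }
  }
  return d;
}

// Deterministic unit vector for coincident agents, seeded by the id pair.
// Keeps fission twins separating reproducibly without touching the RNG stream.
static void tie_break_dir(int id_a, int id_b, double* ux, double* uy) {
  double h = std::sin(id_a * 12.9898 + id_b * 78.233) * 43758.5453;
  double frac = h - std::floor(h);
  double ang = 2.0 * M_PI * frac;
  *ux = std::cos(ang);
  *uy = std::sin(ang);
}

// Forces from the pair potential W(d) = a_rep*exp(-d/l_rep) - a_att*exp(-d/l_att),
// truncated at `cutoff`.  Force on alpha = -grad_alpha sum_beta W(|x_a - x_b|).
// W'(d) = -(a_rep/l_rep) exp(-d/l_rep) + (a_att/l_att) exp(-d/l_att); the radial
// force magnitude is -W'(d) along the separation unit vector (positive = repulsive).
// At d ~ 0 the magnitude is capped at f_max and directed by the id-pair tie-break.
// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(const NumericMatrix& pos, const IntegerVector& ids,
                              double a_rep, double l_rep, double a_att,
                              double l_att, double cutoff, double f_max) {
  int n = pos.nrow();
  NumericMatrix f(n, 2);
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > cutoff) continue;
      double ux, uy, mag;
      if (d < eps) {
        int ia = ids[i] < ids[j] ? ids[i] : ids[j];
        int ib = ids[i] < ids[j] ? ids[j] : ids[i];
        tie_break_dir(ia, ib, &ux, &uy);
        mag = a_rep / l_rep - a_att / l_att; // d -> 0 limit of -W'
        if (mag > f_max) mag = f_max;
        if (mag < -f_max) mag = -f_max;
      } else {
        ux = dx / d;
        uy = dy / d;
        mag = (a_rep / l_rep) * std::exp(-d / l_rep) -
              (a_att / l_att) * std::exp(-d / l_att);
        if (mag > f_max) mag = f_max;
        if (mag < -f_max) mag = -f_max;
      }
      // positive mag pushes i away from j (repulsion); Newton's third law pair
      f(i, 0) += mag * ux;
      f(i, 1) += mag * uy;
      f(j, 0) -= mag * ux;
      f(j, 1) -= mag * uy;
    }
  }
  return f;
}

static double bilinear_one(const NumericMatrix& grid, double ox, double oy,
                           double cell, double x, double y) {
  int nx = grid.nrow(), ny = grid.ncol();
  // outside the domain entirely -> 0
  if (x < ox || y < oy || x > ox + nx * cell || y > oy + ny * cell)
    return 0.0;
  // continuous index in cell-centre space (0-based)
  double gx = (x - ox) / cell - 0.5;
  double gy = (y - oy) / cell - 0.5;
  int i0 = (int)std::floor(gx);
  int j0 = (int)std::floor(gy);
  double tx = gx - i0, ty = gy - j0;
  // clamp to edge cells (flat extrapolation inside the half-cell border)
  if (i0 < 0) { i0 = 0; tx = 0.0; }
  if (j0 < 0) { j0 = 0; ty = 0.0; }
  if (i0 >= nx - 1) { i0 = nx - 2; tx = 1.0; }
  if (j0 >= ny - 1) { j0 = ny - 2; ty = 1.0; }
  if (nx == 1) { i0 = 0; tx = 0.0; }
  if (ny == 1) { j0 = 0; ty = 0.0; }
  int i1 = (nx == 1) ? 0 : i0 + 1;
  int j1 = (ny == 1) ? 0 : j0 + 1;
  double v00 = grid(i0, j0), v10 = grid(i1, j0);
  double v01 = grid(i0, j1), v11 = grid(i1, j1);
  return v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
         v01 * (1 - tx) * ty + v11 * tx * ty;
}

// Bilinear interpolation of a cell-centre grid at arbitrary points; 0 outside.
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& grid, double ox, double oy,
                           double cell, const NumericVector& x,
                           const NumericVector& y) {
  int m = x.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k)
    out[k] = bilinear_one(grid, ox, oy, cell, x[k], y[k]);
  return out;
}

// Central-difference gradient of the bilinear interpolant, step h.
// [[Rcpp::export]]
NumericMatrix cpp_grad(const NumericMatrix& grid, double ox, double oy,
                       double cell, const NumericVector& x,
                       const NumericVector& y, double h) {
  int m = x.size();
  NumericMatrix g(m, 2);
  for (int k = 0; k < m; ++k) {
    g(k, 0) = (bilinear_one(grid, ox, oy, cell, x[k] + h, y[k]) -
               bilinear_one(grid, ox, oy, cell, x[k] - h, y[k])) / (2 * h);
    g(k, 1) = (bilinear_one(grid, ox, oy, cell, x[k], y[k] + h) -
               bilinear_one(grid, ox, oy, cell, x[k], y[k] - h)) / (2 * h);
  }
  return g;
}

// Value of the cell containing each point (nearest-cell lookup); `outside`
// returned for points beyond the grid.  Used for exact friction/barrier tests.
// [[Rcpp::export]]
NumericVector cpp_cell_value(const NumericMatrix& grid, double ox, double oy,
                             double cell, const NumericVector& x,
                             const NumericVector& y, double outside) {
  int nx = grid.nrow(), ny = grid.ncol();
  int m = x.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    int i = (int)std::floor((x[k] - ox) / cell);
    int j = (int)std::floor((y[k] - oy) / cell);
    if (i < 0 || j < 0 || i >= nx || j >= ny)
      out[k] = outside;
    else
      out[k] = grid(i, j);
  }
  return out;
}

// Adoption-rate column for one progressive feature:
// out[a] = sum_b A(a,b) * kernel(s[b] - s[a]), kernel linear or indicator.
// [[Rcpp::export]]
NumericVector cpp_adopt_col(const NumericMatrix& A, const IntegerVector& s,
                            bool linear) {
  int n = s.size();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    double acc = 0.0;
    for (int b = 0; b < n; ++b) {
      int d = s[b] - s[a];
      if (d > 0) acc += A(a, b) * (linear ? d : 1.0);
    }
    out[a] = acc;
  }
  return out;
}

// Copy-rate column for one non-progressive feature:
// out[a] = sum_b A(a,b) * 1[s_b != s_a].
// [[Rcpp::export]]
NumericVector cpp_copy_col(const NumericMatrix& A, const IntegerVector& s) {
  int n = s.size();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    double acc = 0.0;
    for (int b = 0; b < n; ++b)
      if (s[b] != s[a]) acc += A(a, b);
    out[a] = acc;
  }
  return out;
}

// Local population: own members plus neighbours weighted by the fractional
// overlap of two radius-r foraging discs at their centre distance.
// [[Rcpp::export]]
NumericVector cpp_local_pop(const NumericMatrix& pos, const NumericVector& D,
                            double r) {
  int n = pos.nrow();
  NumericVector out(n);
  double area = M_PI * r * r;
  for (int i = 0; i < n; ++i) out[i] = D[i];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= 2 * r) continue;
      double lens = 2 * r * r * std::acos(d / (2 * r)) -
                    (d / 2) * std::sqrt(4 * r * r - d * d);
      double frac = lens / area;
      out[i] += D[j] * frac;
      out[j] += D[i] * frac;
    }
  }
  return out;
}

// Banded interaction network: phi1 within r1, phi2 within r2, 0 beyond.
// [[Rcpp::export]]
NumericMatrix cpp_band_network(const NumericMatrix& pos, double r1, double r2,
                               double phi1, double phi2) {
  int n = pos.nrow();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      double w = d <= r1 ? phi1 : (d <= r2 ? phi2 : 0.0);
      A(i, j) = w;
      A(j, i) = w;
    }
  }
  return A;
}
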