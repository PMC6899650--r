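#include <Rcpp.h>
using namespace Rcpp;

// Pairwise kernels for distance-based summary statistics on axis-aligned
// rectangular windows. Translation edge correction: each (ordered) pair at
// lag v is weighted by 1 / |W ∩ W_v|, which for a rectangle of sides (a, b)
// is 1 / ((a - |dx|) (b - |dy|)).

// Binned pair sums for the PCF and Ripley's K on a rectangle.
// Bin k (1-based) covers distances [(k-1) h, k h), centre r_k = (k - 1/2) h.
// g_num[k] accumulates 1/(2 pi d w) over ordered pairs in bin k;
// k_num[k] accumulates 1/w over ordered pairs with the smallest grid point
// r_j >= d falling at j = k (so cumsum(k_num)[k] = sum over d <= r_k of 1/w).
// [[Rcpp::export]]
List cpp_pair_stats_rect(NumericVector x, NumericVector y,
                         double xmin, double xmax, double ymin, double ymax,
                         int nbins, double h) {
  int n = x.size();
  double a = xmax - xmin, b = ymax - ymin;
  double rmax_g = nbins * h;            // beyond last bin edge: ignored for g
  double rmax_k = (nbins - 0.5) * h;    // last grid point
  NumericVector g_num(nbins), k_num(nbins);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double adx = std::fabs(dx), ady = std::fabs(dy);
      if (adx >= a || ady >= b) continue;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax_g && d > rmax_k) continue;
      double w = (a - adx) * (b - ady);
      if (w <= 0.0) continue;
      if (d < rmax_g && d > 0.0) {
        int bin = (int)(d / h);
        if (bin >= 0 && bin < nbins)
          g_num[bin] += 2.0 / (2.0 * M_PI * d * w);
      }
      if (d <= rmax_k) {
        // smallest k (1-based) with (k - 1/2) h >= d
        int k = (int)std::ceil(d / h + 0.5);
        if (k < 1) k = 1;
        if (k <= nbins) k_num[k - 1] += 2.0 / w;
      }
    }
  }
  return List::create(_["g_num"] = g_num, _["k_num"] = k_num);
}

// Cross-pair version for bivariate statistics; each a-b pair counted once.
// [[Rcpp::export]]
List cpp_cross_stats_rect(NumericVector xa, NumericVector ya,
                          NumericVector xb, NumericVector yb,
                          double xmin, double xmax, double ymin, double ymax,
                          int nbins, double h) {
  int na = xa.size(), nb = xb.size();
  double a = xmax - xmin, b = ymax - ymin;
  double rmax_g = nbins * h;
  double rmax_k = (nbins - 0.5) * h;
  NumericVector g_num(nbins), k_num(nbins);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = xa[i] - xb[j], dy = ya[i] - yb[j];
      double adx = std::fabs(dx), ady = std::fabs(dy);
      if (adx >= a || ady >= b) continue;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax_g && d > rmax_k) continue;
      double w = (a - adx) * (b - ady);
      if (w <= 0.0) continue;
      if (d < rmax_g && d > 0.0) {
        int bin = (int)(d / h);
        if (bin >= 0 && bin < nbins)
          g_num[bin] += 1.0 / (2.0 * M_PI * d * w);
      }
      if (d <= rmax_k) {
        int k = (int)std::ceil(d / h + 0.5);
        if (k < 1) k = 1;
        if (k <= nbins) k_num[k - 1] += 1.0 / w;
      }
    }
  }
  return List::create(_["g_num"] = g_num, _["k_num"] = k_num);
}

// Nearest-neighbour distance for every point (Inf for n = 1).
// [[Rcpp::export]]
NumericVector cpp_nndist(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < out[i]) out[i] = d;
      if (d < out[j]) out[j] = d;
    }
  }
  return out;
}

// Count of (px, py) points within distance R of each query point.
// Bucketed by a uniform grid of cell size R so each query touches only the
// 3x3 neighbouring cells.
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericVector qx, NumericVector qy,
                               NumericVector px, NumericVector py, double R) {
  int nq = qx.size(), np = px.size();
  double R2 = R * R;
  IntegerVector out(nq);
  if (np == 0) return out;
  double xmin = px[0], ymin = py[0], xmax = px[0], ymax = py[0];
  for (int j = 1; j < np; ++j) {
    if (px[j] < xmin) xmin = px[j];
    if (px[j] > xmax) xmax = px[j];
    if (py[j] < ymin) ymin = py[j];
    if (py[j] > ymax) ymax = py[j];
  }
  double cell = R;
  int ncx = (int)((xmax - xmin) / cell) + 1;
  int ncy = (int)((ymax - ymin) / cell) + 1;
  std::vector<std::vector<int> > buckets((size_t)ncx * ncy);
  for (int j = 0; j < np; ++j) {
    int cx = (int)((px[j] - xmin) / cell);
    int cy = (int)((py[j] - ymin) / cell);
    buckets[(size_t)cy * ncx + cx].push_back(j);
  }
  for (int i = 0; i < nq; ++i) {
    int cx = (int)std::floor((qx[i] - xmin) / cell);
    int cy = (int)std::floor((qy[i] - ymin) / cell);
    int c = 0;
    for (int gy = cy - 1; gy <= cy + 1; ++gy) {
      if (gy < 0 || gy >= ncy) continue;
      for (int gx = cx - 1; gx <= cx + 1; ++gx) {
        if (gx < 0 || gx >= ncx) continue;
        const std::vector<int> &b = buckets[(size_t)gy * ncx + gx];
        for (size_t k = 0; k < b.size(); ++k) {
          double dx = qx[i] - px[b[k]], dy = qy[i] - py[b[k]];
          if (dx * dx + dy * dy <= R2) ++c;
        }
      }
    }
    out[i] = c;
  }
  return out;
}

// Signed contribution of one polygon edge to area(disc ∩ polygon), circle
// centred at the origin with radius R (Green's-theorem arc/chord walk).
static double edge_contrib(double ax, double ay, double bx, double by,
                           double R) {
  double dx = bx - ax, dy = by - ay;
  double A = dx * dx + dy * dy;
  if (A == 0.0) return 0.0;
  double B = 2.0 * (ax * dx + ay * dy);
  double C = ax * ax + ay * ay - R * R;
  double ts[4];
  int nt = 0;
  ts[nt++] = 0.0;
  double disc = B * B - 4.0 * A * C;
  if (disc > 0.0) {
    double sq = std::sqrt(disc);
    double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
    if (t1 > 0.0 && t1 < 1.0) ts[nt++] = t1;
    if (t2 > 0.0 && t2 < 1.0) ts[nt++] = t2;
  }
  ts[nt++] = 1.0;
  double total = 0.0;
  for (int s = 0; s + 1 < nt; ++s) {
    double t0 = ts[s], t1 = ts[s + 1];
    double mx = ax + 0.5 * (t0 + t1) * dx, my = ay + 0.5 * (t0 + t1) * dy;
    double p0x = ax + t0 * dx, p0y = ay + t0 * dy;
    double p1x = ax + t1 * dx, p1y = ay + t1 * dy;
    if (mx * mx + my * my <= R * R) {
      total += 0.5 * (p0x * p1y - p0y * p1x);       // triangle O-P0-P1
    } else {
      double ang = std::atan2(p0x * p1y - p0y * p1x, p0x * p1x + p0y * p1y);
      total += 0.5 * R * R * ang;                   // circular sector
    }
  }
  return total;
}

// Area of intersection between discs (centres cx, cy; common radius R) and a
// simple polygon. Returns one area per centre; sign follows |.|.
// [[Rcpp::export]]
NumericVector cpp_circle_poly_area(NumericVector cx, NumericVector cy,
                                   double R,
                                   NumericVector polyx, NumericVector polyy) {
  int nc = cx.size(), m = polyx.size();
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) {
    double s = 0.0;
    for (int e = 0; e < m; ++e) {
      int f = (e + 1) % m;
      s += edge_contrib(polyx[e] - cx[i], polyy[e] - cy[i],
                        polyx[f] - cx[i], polyy[f] - cy[i], R);
    }
    out[i] = std::fabs(s);
  }
  return out;
}
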