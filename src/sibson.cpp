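// Sibson natural-neighbour interpolation by convex polygon clipping.
//
// The virtual Voronoi cell of a query point is built by clipping a large
// bounding frame against the perpendicular bisectors between the query and
// every data site; the Sibson weight of site i is the area this virtual cell
// steals from site i's own Voronoi cell. For queries strictly inside the
// convex hull of the sites the virtual cell is bounded by bisectors alone,
// so the result is independent of the frame.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Pt { double x, y; };
typedef std::vector<Pt> Poly;

// clip convex polygon against half-plane a*x + b*y <= c (Sutherland-Hodgman)
static Poly clip_halfplane(const Poly& poly, double a, double b, double c) {
  Poly out;
  int n = poly.size();
  if (n == 0) return out;
  out.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    const Pt& p = poly[i];
    const Pt& q = poly[(i + 1) % n];
    double fp = a * p.x + b * p.y - c;
    double fq = a * q.x + b * q.y - c;
    if (fp <= 0) out.push_back(p);
    if ((fp < 0 && fq > 0) || (fp > 0 && fq < 0)) {
      double t = fp / (fp - fq);
      Pt r;
      r.x = p.x + t * (q.x - p.x);
      r.y = p.y + t * (q.y - p.y);
      out.push_back(r);
    }
  }
  return out;
}

static double poly_area(const Poly& poly) {
  int n = poly.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const Pt& p = poly[i];
    const Pt& q = poly[(i + 1) % n];
    s += p.x * q.y - q.x * p.y;
  }
  return 0.5 * std::fabs(s);
}

// half-plane of points closer to s than to t: 2(t-s).x <= |t|^2 - |s|^2
static void bisector(double sx, double sy, double tx, double ty,
                     double& a, double& b, double& c) {
  a = 2.0 * (tx - sx);
  b = 2.0 * (ty - sy);
  c = tx * tx + ty * ty - sx * sx - sy * sy;
}

static Poly frame_poly(double xmin, double xmax, double ymin, double ymax) {
  Poly f(4);
  f[0].x = xmin; f[0].y = ymin;
  f[1].x = xmax; f[1].y = ymin;
  f[2].x = xmax; f[2].y = ymax;
  f[3].x = xmin; f[3].y = ymax;
  return f;
}

// Voronoi cell of site i within the frame
static Poly site_cell(int i, const NumericMatrix& sites, const Poly& frame) {
  Poly cell = frame;
  double sx = sites(i, 0), sy = sites(i, 1);
  int n = sites.nrow();
  for (int j = 0; j < n && cell.size() >= 3; ++j) {
    if (j == i) continue;
    double a, b, c;
    bisector(sx, sy, sites(j, 0), sites(j, 1), a, b, c);
    cell = clip_halfplane(cell, a, b, c);
  }
  return cell;
}

// [[Rcpp::export(name = ".sibson_interp_cpp")]]
NumericVector sibson_interp_cpp(NumericMatrix sites, NumericVector values,
                                NumericMatrix queries, NumericVector frame) {
  int n = sites.nrow();
  int m = queries.nrow();
  Poly fr = frame_poly(frame[0], frame[1], frame[2], frame[3]);

  std::vector<Poly> cells(n);
  std::vector<double> bx0(n), bx1(n), by0(n), by1(n);
  for (int i = 0; i < n; ++i) {
    cells[i] = site_cell(i, sites, fr);
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (size_t k = 0; k < cells[i].size(); ++k) {
      x0 = std::min(x0, cells[i][k].x); x1 = std::max(x1, cells[i][k].x);
      y0 = std::min(y0, cells[i][k].y); y1 = std::max(y1, cells[i][k].y);
    }
    bx0[i] = x0; bx1[i] = x1; by0[i] = y0; by1[i] = y1;
  }

  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double qx = queries(q, 0), qy = queries(q, 1);

    // coincident with a site -> exact value
    int hit = -1;
    for (int i = 0; i < n; ++i) {
      double dx = qx - sites(i, 0), dy = qy - sites(i, 1);
      if (dx * dx + dy * dy < 1e-18) { hit = i; break; }
    }
    if (hit >= 0) { out[q] = values[hit]; continue; }

    Poly vc = fr;
    for (int j = 0; j < n && vc.size() >= 3; ++j) {
      double a, b, c;
      bisector(qx, qy, sites(j, 0), sites(j, 1), a, b, c);
      vc = clip_halfplane(vc, a, b, c);
    }
    double qx0 = R_PosInf, qx1 = R_NegInf, qy0 = R_PosInf, qy1 = R_NegInf;
    for (size_t k = 0; k < vc.size(); ++k) {
      qx0 = std::min(qx0, vc[k].x); qx1 = std::max(qx1, vc[k].x);
      qy0 = std::min(qy0, vc[k].y); qy1 = std::max(qy1, vc[k].y);
    }

    double wsum = 0.0, vsum = 0.0;
    for (int i = 0; i < n; ++i) {
      if (bx1[i] < qx0 || bx0[i] > qx1 || by1[i] < qy0 || by0[i] > qy1) continue;
      Poly inter = vc;
      const Poly& cell = cells[i];
      int cn = cell.size();
      for (int e = 0; e < cn && inter.size() >= 3; ++e) {
        const Pt& p = cell[e];
        const Pt& r = cell[(e + 1) % cn];
        // interior of a CCW cell is on the left of each edge:
        // outward normal (dy, -dx), keep a*x + b*y <= c
        double a = r.y - p.y;
        double b = -(r.x - p.x);
        double c = a * p.x + b * p.y;
        inter = clip_halfplane(inter, a, b, c);
      }
      double w = poly_area(inter);
      if (w > 0) { wsum += w; vsum += w * values[i]; }
    }
    if (wsum <= 0) {
      // fallback: nearest site
      double best = R_PosInf; int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dx = qx - sites(i, 0), dy = qy - sites(i, 1);
        double d = dx * dx + dy * dy;
        if (d < best) { best = d; bi = i; }
      }
      out[q] = values[bi];
    } else {
      out[q] = vsum / wsum;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".voronoi_cells_cpp")]]
List voronoi_cells_cpp(NumericMatrix sites, NumericVector frame) {
  int n = sites.nrow();
  Poly fr = frame_poly(frame[0], frame[1], frame[2], frame[3]);
  List out(n);
  for (int i = 0; i < n; ++i) {
    Poly cell = site_cell(i, sites, fr);
    NumericMatrix m(cell.size(), 2);
    for (size_t k = 0; k < cell.size(); ++k) {
      m(k, 0) = cell[k].x;
      m(k, 1) = cell[k].y;
    }
    out[i] = m;
  }
  return out;
}
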