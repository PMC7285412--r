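#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Squared distance from point p to triangle (a, b, c), Eberly-style:
// minimize |a + s e0 + t e1 - p|^2 over the unit-triangle domain.
static double tri_dist2(const double *p, const double *a, const double *b,
                        const double *c) {
  double e0[3], e1[3], d[3];
  for (int i = 0; i < 3; ++i) {
    e0[i] = b[i] - a[i];
    e1[i] = c[i] - a[i];
    d[i] = a[i] - p[i];
  }
  double A = e0[0] * e0[0] + e0[1] * e0[1] + e0[2] * e0[2];
  double B = e0[0] * e1[0] + e0[1] * e1[1] + e0[2] * e1[2];
  double C = e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2];
  double D = e0[0] * d[0] + e0[1] * d[1] + e0[2] * d[2];
  double E = e1[0] * d[0] + e1[1] * d[1] + e1[2] * d[2];
  double det = A * C - B * B;
  double s = B * E - C * D, t = B * D - A * E;

  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { // region 4
        if (D < 0) { t = 0; s = (-D >= A ? 1 : -D / A); }
        else { s = 0; t = (E >= 0 ? 0 : (-E >= C ? 1 : -E / C)); }
      } else { // region 3
        s = 0; t = (E >= 0 ? 0 : (-E >= C ? 1 : -E / C));
      }
    } else if (t < 0) { // region 5
      t = 0; s = (D >= 0 ? 0 : (-D >= A ? 1 : -D / A));
    } else { // region 0
      double inv = 1.0 / det; s *= inv; t *= inv;
    }
  } else {
    if (s < 0) { // region 2
      double tmp0 = B + D, tmp1 = C + E;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = A - 2 * B + C;
        s = (numer >= denom ? 1 : numer / denom); t = 1 - s;
      } else { s = 0; t = (tmp1 <= 0 ? 1 : (E >= 0 ? 0 : -E / C)); }
    } else if (t < 0) { // region 6
      double tmp0 = B + E, tmp1 = A + D;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = A - 2 * B + C;
        t = (numer >= denom ? 1 : numer / denom); s = 1 - t;
      } else { t = 0; s = (tmp1 <= 0 ? 1 : (D >= 0 ? 0 : -D / A)); }
    } else { // region 1
      double numer = (C + E) - (B + D);
      if (numer <= 0) s = 0;
      else { double denom = A - 2 * B + C; s = (numer >= denom ? 1 : numer / denom); }
      t = 1 - s;
    }
  }
  double q[3];
  for (int i = 0; i < 3; ++i) q[i] = a[i] + s * e0[i] + t * e1[i] - p[i];
  return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
}

// Unsigned Euclidean distance from each point to the nearest point of the
// triangle mesh (interior, edge, or vertex). Triangles are binned on a
// uniform lateral (x, y) grid; queries search outward ring by ring and stop
// once the lateral lower bound exceeds the best distance found.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix points, NumericMatrix vertices,
                                  IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow(), nv = vertices.nrow();
  if (nf == 0 || nv == 0) stop("empty mesh");
  std::vector<double> V(3 * nv), P(3 * np);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V[3 * i + k] = vertices(i, k);
  for (int i = 0; i < np; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = points(i, k);

  // lateral bounding box of the mesh
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < nv; ++i) {
    xmin = std::min(xmin, V[3 * i]); xmax = std::max(xmax, V[3 * i]);
    ymin = std::min(ymin, V[3 * i + 1]); ymax = std::max(ymax, V[3 * i + 1]);
  }
  int ng = std::max(1, std::min(512, (int)std::floor(std::sqrt((double)nf / 2))));
  double cw = std::max({(xmax - xmin) / ng, (ymax - ymin) / ng, 1e-12});
  int ncx = std::max(1, (int)std::ceil((xmax - xmin) / cw));
  int ncy = std::max(1, (int)std::ceil((ymax - ymin) / cw));

  std::vector<std::vector<int>> cells((size_t)ncx * ncy);
  for (int f = 0; f < nf; ++f) {
    double bx0 = R_PosInf, bx1 = R_NegInf, by0 = R_PosInf, by1 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      const double *v = &V[3 * (faces(f, k) - 1)];
      bx0 = std::min(bx0, v[0]); bx1 = std::max(bx1, v[0]);
      by0 = std::min(by0, v[1]); by1 = std::max(by1, v[1]);
    }
    int cx0 = std::min(ncx - 1, std::max(0, (int)((bx0 - xmin) / cw)));
    int cx1 = std::min(ncx - 1, std::max(0, (int)((bx1 - xmin) / cw)));
    int cy0 = std::min(ncy - 1, std::max(0, (int)((by0 - ymin) / cw)));
    int cy1 = std::min(ncy - 1, std::max(0, (int)((by1 - ymin) / cw)));
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        cells[(size_t)cy * ncx + cx].push_back(f);
  }

  NumericVector out(np);
  int maxring = std::max(ncx, ncy);
  for (int i = 0; i < np; ++i) {
    const double *p = &P[3 * i];
    int pcx = std::min(ncx - 1, std::max(0, (int)((p[0] - xmin) / cw)));
    int pcy = std::min(ncy - 1, std::max(0, (int)((p[1] - ymin) / cw)));
    double best = R_PosInf;
    for (int r = 0; r <= maxring; ++r) {
      // lateral lower bound for cells in ring r (in-cell position conservative)
      if (r >= 2) {
        double lb = (r - 1) * cw;
        if (lb * lb > best) break;
      }
      bool any = false;
      for (int cx = pcx - r; cx <= pcx + r; ++cx) {
        if (cx < 0 || cx >= ncx) continue;
        for (int cy = pcy - r; cy <= pcy + r; ++cy) {
          if (cy < 0 || cy >= ncy) continue;
          if (std::max(std::abs(cx - pcx), std::abs(cy - pcy)) != r) continue;
          any = true;
          const std::vector<int> &cell = cells[(size_t)cy * ncx + cx];
          for (size_t ci = 0; ci < cell.size(); ++ci) {
            int f = cell[ci];
            double d2 = tri_dist2(p, &V[3 * (faces(f, 0) - 1)],
                                  &V[3 * (faces(f, 1) - 1)],
                                  &V[3 * (faces(f, 2) - 1)]);
            if (d2 < best) best = d2;
          }
        }
      }
      if (!any && r > maxring) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
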