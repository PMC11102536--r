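#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// For each query point, the exact nearest point on any triangle of the
// mesh, accelerated by a uniform grid over triangle bounding boxes with
// expanding-shell search. Ties broken by lowest face index (strict
// improvement required while scanning faces in ascending index order
// within each cell; across cells the first-found equal-distance winner
// keeps the lower index because candidate lists are merged in index
// order). Returns list(points = n x 3, dist2 = n, face = n, 1-based).
// [[Rcpp::export]]
List closest_points_on_mesh(NumericMatrix query, NumericMatrix vertices,
                            IntegerMatrix faces) {
  const int nq = query.nrow();
  const int nf = faces.nrow();
  const int nv = vertices.nrow();
  if (nf < 1 || nv < 3) stop("mesh too small");

  std::vector<double> ta(3 * nf), tb(3 * nf), tc(3 * nf);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double avg_edge = 0.0;
  for (int j = 0; j < nf; ++j) {
    int ia = faces(j, 0) - 1, ib = faces(j, 1) - 1, ic = faces(j, 2) - 1;
    if (ia < 0 || ib < 0 || ic < 0 || ia >= nv || ib >= nv || ic >= nv)
      stop("face index out of range");
    for (int k = 0; k < 3; ++k) {
      ta[3 * j + k] = vertices(ia, k);
      tb[3 * j + k] = vertices(ib, k);
      tc[3 * j + k] = vertices(ic, k);
      double mn = std::min(ta[3 * j + k],
                           std::min(tb[3 * j + k], tc[3 * j + k]));
      double mx = std::max(ta[3 * j + k],
                           std::max(tb[3 * j + k], tc[3 * j + k]));
      if (mn < lo[k]) lo[k] = mn;
      if (mx > hi[k]) hi[k] = mx;
    }
    double e = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = ta[3 * j + k] - tb[3 * j + k];
      e += d * d;
    }
    avg_edge += std::sqrt(e);
  }
  avg_edge /= nf;
  double h = std::max(avg_edge, 1e-6);  // cell size ~ mean edge length

  int dim[3];
  for (int k = 0; k < 3; ++k) {
    dim[k] = std::max(1, std::min(128,
      (int)std::floor((hi[k] - lo[k]) / h) + 1));
  }
  // recompute per-axis cell width to cover the extent exactly
  double cw[3];
  for (int k = 0; k < 3; ++k) {
    cw[k] = std::max((hi[k] - lo[k]) / dim[k], 1e-9);
  }
  double minw = std::min(cw[0], std::min(cw[1], cw[2]));
  const long ncell = (long)dim[0] * dim[1] * dim[2];

  // bucket triangles into every cell their bbox overlaps (counting sort)
  std::vector<int> count(ncell + 1, 0);
  std::vector<int> c0(nf), c1(nf), r0(nf), r1(nf), s0(nf), s1(nf);
  for (int j = 0; j < nf; ++j) {
    int cl[3], ch[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(ta[3 * j + k],
                           std::min(tb[3 * j + k], tc[3 * j + k]));
      double mx = std::max(ta[3 * j + k],
                           std::max(tb[3 * j + k], tc[3 * j + k]));
      cl[k] = std::max(0, std::min(dim[k] - 1,
               (int)std::floor((mn - lo[k]) / cw[k])));
      ch[k] = std::max(0, std::min(dim[k] - 1,
               (int)std::floor((mx - lo[k]) / cw[k])));
    }
    c0[j] = cl[0]; c1[j] = ch[0];
    r0[j] = cl[1]; r1[j] = ch[1];
    s0[j] = cl[2]; s1[j] = ch[2];
    for (int x = cl[0]; x <= ch[0]; ++x)
      for (int y = cl[1]; y <= ch[1]; ++y)
        for (int z = cl[2]; z <= ch[2]; ++z)
          count[(long)x + dim[0] * ((long)y + dim[1] * z) + 1]++;
  }
  for (long c = 0; c < ncell; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(count[ncell]);
  std::vector<int> fill(count.begin(), count.end() - 1);
  for (int j = 0; j < nf; ++j) {
    for (int x = c0[j]; x <= c1[j]; ++x)
      for (int y = r0[j]; y <= r1[j]; ++y)
        for (int z = s0[j]; z <= s1[j]; ++z)
          bucket[fill[(long)x + dim[0] * ((long)y + dim[1] * z)]++] = j;
  }

  NumericMatrix out(nq, 3);
  NumericVector dist2(nq);
  IntegerVector face(nq);
  std::vector<int> stamp(nf, -1);
  double q[3], best[3], cand[3];
  int maxdim = std::max(dim[0], std::max(dim[1], dim[2]));

  for (int i = 0; i < nq; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    int cc[3];
    for (int k = 0; k < 3; ++k) {
      cc[k] = std::max(0, std::min(dim[k] - 1,
               (int)std::floor((q[k] - lo[k]) / cw[k])));
    }
    double bestd2 = R_PosInf;
    int bestf = -1;
    for (int ring = 0; ring <= maxdim; ++ring) {
      // any triangle in an unscanned shell is at least (ring-1)*minw away
      if (bestf >= 0) {
        double guard = (double)(ring - 1) * minw;
        if (guard > 0 && guard * guard >= bestd2) break;
      }
      bool any_cell = false;
      int x0 = cc[0] - ring, x1 = cc[0] + ring;
      int y0 = cc[1] - ring, y1 = cc[1] + ring;
      int z0 = cc[2] - ring, z1 = cc[2] + ring;
      for (int x = x0; x <= x1; ++x) {
        if (x < 0 || x >= dim[0]) continue;
        for (int y = y0; y <= y1; ++y) {
          if (y < 0 || y >= dim[1]) continue;
          for (int z = z0; z <= z1; ++z) {
            if (z < 0 || z >= dim[2]) continue;
            // shell only: skip interior cells already scanned
            if (ring > 0 && x != x0 && x != x1 && y != y0 && y != y1 &&
                z != z0 && z != z1) continue;
            any_cell = true;
            long cell = (long)x + dim[0] * ((long)y + dim[1] * z);
            for (int bi = count[cell]; bi < count[cell + 1]; ++bi) {
              int j = bucket[bi];
              if (stamp[j] == i) continue;
              stamp[j] = i;
              closest_on_tri(q, &ta[3 * j], &tb[3 * j], &tc[3 * j], cand);
              double ex = q[0] - cand[0], ey = q[1] - cand[1],
                     ez = q[2] - cand[2];
              double d2 = ex * ex + ey * ey + ez * ez;
              if (d2 < bestd2 || (d2 == bestd2 && j < bestf)) {
                bestd2 = d2;
                bestf = j;
                best[0] = cand[0]; best[1] = cand[1]; best[2] = cand[2];
              }
            }
          }
        }
      }
      if (!any_cell && ring > maxdim) break;
    }
    out(i, 0) = best[0]; out(i, 1) = best[1]; out(i, 2) = best[2];
    dist2[i] = bestd2;
    face[i] = bestf + 1;
  }
  return List::create(_["points"] = out, _["dist2"] = dist2,
                      _["face"] = face);
}
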