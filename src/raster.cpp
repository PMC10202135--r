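#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double norm3(double x, double y, double z) {
  return std::sqrt(x * x + y * y + z * z);
}

// Z-buffer rasterization of a triangle soup over the soil plane z = 0.
//
// V        n x 3 world-space vertices (mm)
// F        m x 3 zero-based vertex indices
// owner_id m     per-face primitive owner (>= 1 for leaves; 0 = soil is implicit)
// UV       n x 2 per-vertex texture coordinates (mm along / across the blade)
// cam_pos  camera centre (mm), R 3x3 world->camera rotation (rows = camera axes)
// fx,fy    focal lengths in px, cx,cy principal point in px
//
// Pixel centres sit at integer coordinates, origin top-left, u rightward,
// v downward. Depth is the Euclidean distance from the camera centre.
// Ties in depth are broken toward the smaller owner id so the result does
// not depend on triangle order.
// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix V, IntegerMatrix F, IntegerVector owner_id,
                   NumericMatrix UV, NumericVector cam_pos, NumericMatrix R,
                   double fx, double fy, double cx, double cy, int W, int H) {
  NumericMatrix depth(H, W), tu(H, W), tv(H, W);
  NumericMatrix nx(H, W), ny(H, W), nz(H, W);
  NumericMatrix px(H, W), py(H, W), pz(H, W);
  IntegerMatrix owner(H, W);
  int degenerate = 0;

  // soil pass: analytic ray / plane intersection per pixel
  for (int v = 0; v < H; ++v) {
    for (int u = 0; u < W; ++u) {
      double dcx = (u - cx) / fx, dcy = (v - cy) / fy, dcz = 1.0;
      double dx = R(0, 0) * dcx + R(1, 0) * dcy + R(2, 0) * dcz;
      double dy = R(0, 1) * dcx + R(1, 1) * dcy + R(2, 1) * dcz;
      double dz = R(0, 2) * dcx + R(1, 2) * dcy + R(2, 2) * dcz;
      double dn = norm3(dx, dy, dz);
      dx /= dn; dy /= dn; dz /= dn;
      if (dz < -1e-12 && cam_pos[2] > 0) {
        double t = -cam_pos[2] / dz;
        depth(v, u) = t;
        owner(v, u) = 0;
        px(v, u) = cam_pos[0] + t * dx;
        py(v, u) = cam_pos[1] + t * dy;
        pz(v, u) = 0.0;
        nx(v, u) = 0.0; ny(v, u) = 0.0; nz(v, u) = 1.0;
        tu(v, u) = px(v, u); tv(v, u) = py(v, u);
      } else {
        depth(v, u) = R_PosInf;
        owner(v, u) = -1;
      }
    }
  }

  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int idx[3] = { F(f, 0), F(f, 1), F(f, 2) };
    double wx[3], wy[3], wz[3], camx[3], camy[3], camz[3];
    bool behind = false;
    for (int k = 0; k < 3; ++k) {
      wx[k] = V(idx[k], 0); wy[k] = V(idx[k], 1); wz[k] = V(idx[k], 2);
      double ox = wx[k] - cam_pos[0], oy = wy[k] - cam_pos[1], oz = wz[k] - cam_pos[2];
      camx[k] = R(0, 0) * ox + R(0, 1) * oy + R(0, 2) * oz;
      camy[k] = R(1, 0) * ox + R(1, 1) * oy + R(1, 2) * oz;
      camz[k] = R(2, 0) * ox + R(2, 1) * oy + R(2, 2) * oz;
      if (camz[k] < 1e-6) behind = true;
    }
    if (behind) continue;

    // world-space face normal (flat shading)
    double e1x = wx[1] - wx[0], e1y = wy[1] - wy[0], e1z = wz[1] - wz[0];
    double e2x = wx[2] - wx[0], e2y = wy[2] - wy[0], e2z = wz[2] - wz[0];
    double fnx = e1y * e2z - e1z * e2y;
    double fny = e1z * e2x - e1x * e2z;
    double fnz = e1x * e2y - e1y * e2x;
    double fnn = norm3(fnx, fny, fnz);
    if (fnn < 1e-9) { ++degenerate; continue; }
    fnx /= fnn; fny /= fnn; fnz /= fnn;

    double su[3], sv[3];
    for (int k = 0; k < 3; ++k) {
      su[k] = cx + fx * camx[k] / camz[k];
      sv[k] = cy + fy * camy[k] / camz[k];
    }
    double D = (sv[1] - sv[2]) * (su[0] - su[2]) + (su[2] - su[1]) * (sv[0] - sv[2]);
    if (std::fabs(D) < 1e-12) { ++degenerate; continue; }

    int umin = std::max(0, (int)std::floor(std::min({ su[0], su[1], su[2] })));
    int umax = std::min(W - 1, (int)std::ceil(std::max({ su[0], su[1], su[2] })));
    int vmin = std::max(0, (int)std::floor(std::min({ sv[0], sv[1], sv[2] })));
    int vmax = std::min(H - 1, (int)std::ceil(std::max({ sv[0], sv[1], sv[2] })));
    if (umin > umax || vmin > vmax) continue;

    int oid = owner_id[f];
    for (int v = vmin; v <= vmax; ++v) {
      for (int u = umin; u <= umax; ++u) {
        double l0 = ((sv[1] - sv[2]) * (u - su[2]) + (su[2] - su[1]) * (v - sv[2])) / D;
        double l1 = ((sv[2] - sv[0]) * (u - su[2]) + (su[0] - su[2]) * (v - sv[2])) / D;
        double l2 = 1.0 - l0 - l1;
        if (l0 < -1e-9 || l1 < -1e-9 || l2 < -1e-9) continue;
        // perspective-correct barycentric weights
        double q0 = l0 / camz[0], q1 = l1 / camz[1], q2 = l2 / camz[2];
        double qs = q0 + q1 + q2;
        double b0 = q0 / qs, b1 = q1 / qs, b2 = q2 / qs;
        double Px = b0 * wx[0] + b1 * wx[1] + b2 * wx[2];
        double Py = b0 * wy[0] + b1 * wy[1] + b2 * wy[2];
        double Pz = b0 * wz[0] + b1 * wz[1] + b2 * wz[2];
        double d = norm3(Px - cam_pos[0], Py - cam_pos[1], Pz - cam_pos[2]);
        double zb = depth(v, u);
        int ob = owner(v, u);
        if (d < zb || (d == zb && oid < ob)) {
          depth(v, u) = d;
          owner(v, u) = oid;
          px(v, u) = Px; py(v, u) = Py; pz(v, u) = Pz;
          nx(v, u) = fnx; ny(v, u) = fny; nz(v, u) = fnz;
          tu(v, u) = b0 * UV(idx[0], 0) + b1 * UV(idx[1], 0) + b2 * UV(idx[2], 0);
          tv(v, u) = b0 * UV(idx[0], 1) + b1 * UV(idx[1], 1) + b2 * UV(idx[2], 1);
        }
      }
    }
  }

  return List::create(
    _["depth"] = depth, _["owner"] = owner,
    _["tu"] = tu, _["tv"] = tv,
    _["nx"] = nx, _["ny"] = ny, _["nz"] = nz,
    _["px"] = px, _["py"] = py, _["pz"] = pz,
    _["degenerate"] = degenerate);
}

// Any-hit ray test (Moller-Trumbore) of rays origins[i] + t * dir against a
// triangle soup, counting hits with t in (tmin, Inf). Used for hard shadows.
// dir may be a single direction recycled over all origins.
// [[Rcpp::export]]
LogicalVector cpp_any_hit(NumericMatrix origins, NumericMatrix dirs,
                          NumericMatrix V, IntegerMatrix F, double tmin) {
  int np = origins.nrow(), nf = F.nrow();
  bool single_dir = (dirs.nrow() == 1);
  LogicalVector hit(np);

  // precompute triangle vertices and edges
  std::vector<double> ax(nf), ay(nf), az(nf), e1x(nf), e1y(nf), e1z(nf),
      e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
    ax[f] = V(i0, 0); ay[f] = V(i0, 1); az[f] = V(i0, 2);
    e1x[f] = V(i1, 0) - ax[f]; e1y[f] = V(i1, 1) - ay[f]; e1z[f] = V(i1, 2) - az[f];
    e2x[f] = V(i2, 0) - ax[f]; e2y[f] = V(i2, 1) - ay[f]; e2z[f] = V(i2, 2) - az[f];
  }

  for (int i = 0; i < np; ++i) {
    double ox = origins(i, 0), oy = origins(i, 1), oz = origins(i, 2);
    double dx, dy, dz;
    if (single_dir) { dx = dirs(0, 0); dy = dirs(0, 1); dz = dirs(0, 2); }
    else            { dx = dirs(i, 0); dy = dirs(i, 1); dz = dirs(i, 2); }
    bool h = false;
    for (int f = 0; f < nf && !h; ++f) {
      double hx = dy * e2z[f] - dz * e2y[f];
      double hy = dz * e2x[f] - dx * e2z[f];
      double hz = dx * e2y[f] - dy * e2x[f];
      double a = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(a) < 1e-12) continue;
      double inv = 1.0 / a;
      double sx = ox - ax[f], sy = oy - ay[f], sz = oz - az[f];
      double uu = inv * (sx * hx + sy * hy + sz * hz);
      if (uu < 0.0 || uu > 1.0) continue;
      double qx = sy * e1z[f] - sz * e1y[f];
      double qy = sz * e1x[f] - sx * e1z[f];
      double qz = sx * e1y[f] - sy * e1x[f];
      double vv = inv * (dx * qx + dy * qy + dz * qz);
      if (vv < 0.0 || uu + vv > 1.0) continue;
      double t = inv * (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz);
      if (t > tmin) h = true;
    }
    hit[i] = h;
  }
  return hit;
}
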