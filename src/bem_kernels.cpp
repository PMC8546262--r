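// Analytic boundary-element kernels for the nested-compartment forward model.
//
// The double-layer potential of a linear (vertex-based) density over a plane
// triangle has a closed form built from the triangle's solid angle (van
// Oosterom & Strackee) and edge logarithms: with the observation point at the
// origin and the triangle in a plane at signed distance d = y.n,
//
//   int_T N_i(x) (x . n)/|x|^3 dS = alpha_i * Omega + d * beta_i . Sx,
//   Sx = n * Omega - sum_edges m_e * gamma_e,
//
// where N_i = alpha_i + beta_i . x is the linear shape function of vertex i,
// m_e = t_e x n the in-plane outward edge normal and gamma_e the line
// integral of 1/|x| along the edge. When the observation point lies in the
// triangle's plane (d = 0, in particular for every triangle touching the
// collocation vertex) the kernel vanishes identically, which is exactly the
// principal-value treatment collocation requires.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec3 row3(const arma::mat& M, arma::uword i) {
  return arma::vec3({M(i, 0), M(i, 1), M(i, 2)});
}

// [[Rcpp::export(name = ".bem_collocation_matrix")]]
arma::mat bem_collocation_matrix(const arma::mat& vertices,
                                 const arma::imat& triangles,
                                 const arma::mat& obs) {
  const arma::uword nv = vertices.n_rows;
  const arma::uword nt = triangles.n_rows;
  const arma::uword no = obs.n_rows;
  arma::mat D(no, nv, arma::fill::zeros);

  for (arma::uword t = 0; t < nt; ++t) {
    const arma::uword i1 = triangles(t, 0) - 1;
    const arma::uword i2 = triangles(t, 1) - 1;
    const arma::uword i3 = triangles(t, 2) - 1;
    const arma::vec3 v1 = row3(vertices, i1);
    const arma::vec3 v2 = row3(vertices, i2);
    const arma::vec3 v3 = row3(vertices, i3);

    const arma::vec3 e12 = v2 - v1, e13 = v3 - v1;
    arma::vec3 nrm = arma::cross(e12, e13);
    const double twoA = arma::norm(nrm);
    if (twoA <= 0.0) stop("degenerate triangle in mesh");
    nrm /= twoA;
    // shape-function gradients (in-plane), independent of observation point
    const arma::vec3 b1 = arma::cross(nrm, v3 - v2) / twoA;
    const arma::vec3 b2 = arma::cross(nrm, v1 - v3) / twoA;
    const arma::vec3 b3 = arma::cross(nrm, v2 - v1) / twoA;
    const double scale = std::sqrt(twoA);

    for (arma::uword o = 0; o < no; ++o) {
      const arma::vec3 p = row3(obs, o);
      const arma::vec3 y1 = v1 - p, y2 = v2 - p, y3 = v3 - p;
      const double d = arma::dot(y1, nrm);
      if (std::abs(d) < 1e-9 * scale) continue;  // coplanar: kernel vanishes

      const double n1 = arma::norm(y1), n2 = arma::norm(y2), n3 = arma::norm(y3);
      const double num = arma::dot(y1, arma::cross(y2, y3));
      const double den = n1 * n2 * n3 + arma::dot(y1, y2) * n3 +
                         arma::dot(y1, y3) * n2 + arma::dot(y2, y3) * n1;
      const double omega = 2.0 * std::atan2(num, den);

      // edge line integrals of 1/|x|
      arma::vec3 S = nrm * omega;
      const arma::vec3 ya[3] = {y1, y2, y3};
      const arma::vec3 yb[3] = {y2, y3, y1};
      for (int e = 0; e < 3; ++e) {
        arma::vec3 tv = yb[e] - ya[e];
        const double len = arma::norm(tv);
        tv /= len;
        const double na = arma::norm(ya[e]), nb = arma::norm(yb[e]);
        const double gamma = std::log((nb + arma::dot(tv, yb[e])) /
                                      (na + arma::dot(tv, ya[e])));
        S -= arma::cross(tv, nrm) * gamma;
      }

      const double a1 = 1.0 - arma::dot(b1, y1);
      const double a2 = 1.0 - arma::dot(b2, y2);
      const double a3 = 1.0 - arma::dot(b3, y3);
      D(o, i1) += a1 * omega + d * arma::dot(b1, S);
      D(o, i2) += a2 * omega + d * arma::dot(b2, S);
      D(o, i3) += a3 * omega + d * arma::dot(b3, S);
    }
  }
  return D;
}

// Generalized winding number (total signed solid angle / 4 pi) of a closed
// triangulated surface seen from each query point: ~1 inside, ~0 outside.
// [[Rcpp::export(name = ".mesh_winding_number")]]
arma::vec mesh_winding_number(const arma::mat& points,
                              const arma::mat& vertices,
                              const arma::imat& triangles) {
  const arma::uword np = points.n_rows, nt = triangles.n_rows;
  arma::vec w(np, arma::fill::zeros);
  for (arma::uword t = 0; t < nt; ++t) {
    const arma::vec3 v1 = row3(vertices, triangles(t, 0) - 1);
    const arma::vec3 v2 = row3(vertices, triangles(t, 1) - 1);
    const arma::vec3 v3 = row3(vertices, triangles(t, 2) - 1);
    for (arma::uword p = 0; p < np; ++p) {
      const arma::vec3 q = row3(points, p);
      const arma::vec3 y1 = v1 - q, y2 = v2 - q, y3 = v3 - q;
      const double n1 = arma::norm(y1), n2 = arma::norm(y2), n3 = arma::norm(y3);
      const double num = arma::dot(y1, arma::cross(y2, y3));
      const double den = n1 * n2 * n3 + arma::dot(y1, y2) * n3 +
                         arma::dot(y1, y3) * n2 + arma::dot(y2, y3) * n1;
      w(p) += 2.0 * std::atan2(num, den);
    }
  }
  return w / (4.0 * arma::datum::pi);
}

// Closest point on a triangulated surface for each query point.
// Returns triangle index (1-based), barycentric coordinates and distance.
// [[Rcpp::export(name = ".project_points_to_mesh")]]
List project_points_to_mesh(const arma::mat& points,
                            const arma::mat& vertices,
                            const arma::imat& triangles) {
  const arma::uword np = points.n_rows, nt = triangles.n_rows;
  arma::ivec tri_id(np);
  arma::mat bary(np, 3), proj(np, 3);
  arma::vec dist(np);
  dist.fill(arma::datum::inf);

  for (arma::uword t = 0; t < nt; ++t) {
    const arma::vec3 a = row3(vertices, triangles(t, 0) - 1);
    const arma::vec3 b = row3(vertices, triangles(t, 1) - 1);
    const arma::vec3 c = row3(vertices, triangles(t, 2) - 1);
    const arma::vec3 ab = b - a, ac = c - a;
    for (arma::uword p = 0; p < np; ++p) {
      const arma::vec3 q = row3(points, p);
      // Ericson's closest-point-on-triangle
      const arma::vec3 ap = q - a;
      const double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
      double u, v;  // barycentric weights of b and c
      if (d1 <= 0 && d2 <= 0) { u = 0; v = 0; }
      else {
        const arma::vec3 bp = q - b;
        const double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
        if (d3 >= 0 && d4 <= d3) { u = 1; v = 0; }
        else {
          const arma::vec3 cp = q - c;
          const double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
          if (d6 >= 0 && d5 <= d6) { u = 0; v = 1; }
          else {
            const double vc = d1 * d4 - d3 * d2;
            if (vc <= 0 && d1 >= 0 && d3 <= 0) { u = d1 / (d1 - d3); v = 0; }
            else {
              const double vb = d5 * d2 - d1 * d6;
              if (vb <= 0 && d2 >= 0 && d6 <= 0) { u = 0; v = d2 / (d2 - d6); }
              else {
                const double va = d3 * d6 - d5 * d4;
                if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
                  const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
                  u = 1 - w; v = w;
                } else {
                  const double denom = 1.0 / (va + vb + vc);
                  u = vb * denom; v = vc * denom;
                }
              }
            }
          }
        }
      }
      const arma::vec3 cp = a + ab * u + ac * v;
      const double dd = arma::norm(q - cp);
      if (dd < dist(p)) {
        dist(p) = dd;
        tri_id(p) = static_cast<int>(t) + 1;
        bary(p, 0) = 1 - u - v; bary(p, 1) = u; bary(p, 2) = v;
        proj.row(p) = cp.t();
      }
    }
  }
  return List::create(_["triangle"] = tri_id, _["bary"] = bary,
                      _["point"] = proj, _["distance"] = dist);
}
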