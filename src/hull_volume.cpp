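// Exact convex hull volume in low dimension by supporting-hyperplane
// enumeration. Every d-subset of points defines a candidate hyperplane; a
// facet is a hyperplane with all points on one side. The hull volume is the
// sum over facets of pyramid volumes with apex at the centroid. Facets
// carrying more than d points (cohyperplanar, e.g. hypercube faces) are
// projected into their flat and handled by recursion, so the result is exact
// for degenerate configurations too. Intended for small point sets
// (m up to a few dozen, d <= 6): cost is C(m, d) hyperplane tests.
#include <RcppArmadillo.h>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double factorial_d(const uword k) {
  double f = 1.0;
  for (uword i = 2; i <= k; ++i) f *= static_cast<double>(i);
  return f;
}

// (d-1)-volume of the simplex with d vertices (rows of V) embedded in R^d,
// via the Gram determinant of its edge vectors.
static double facet_simplex_volume(const mat& V) {
  mat E = V.rows(1, V.n_rows - 1);
  E.each_row() -= V.row(0);
  const double g = det(E * E.t());
  if (g <= 0.0) return 0.0;
  return std::sqrt(g) / factorial_d(V.n_rows - 1);
}

// Normal of the hyperplane through the d rows of A (d x d), by cofactor
// expansion of the (d-1) x d edge matrix (generalized cross product).
static vec hyperplane_normal(const mat& A) {
  const uword d = A.n_cols;
  mat B = A.rows(1, d - 1);
  B.each_row() -= A.row(0);
  vec nrm(d);
  double sgn = 1.0;
  for (uword j = 0; j < d; ++j) {
    mat M(d - 1, d - 1);
    uword cc = 0;
    for (uword c2 = 0; c2 < d; ++c2) {
      if (c2 == j) continue;
      M.col(cc++) = B.col(c2);
    }
    nrm(j) = sgn * det(M);
    sgn = -sgn;
  }
  return nrm;
}

static double hull_volume_rec(const mat& P) {
  const uword m = P.n_rows, d = P.n_cols;
  if (d == 1) {
    if (m == 0) return 0.0;
    return P.col(0).max() - P.col(0).min();
  }
  if (m < d + 1) return 0.0;

  const double scale = std::max(1.0, abs(P).max());
  const double tol = 1e-9 * scale;
  const double ntol = 1e-10 * std::pow(scale, static_cast<double>(d - 1));
  const rowvec cen = mean(P, 0);

  std::vector<uword> idx(d);
  for (uword i = 0; i < d; ++i) idx[i] = i;
  std::set<std::vector<long long>> seen;
  double vol = 0.0;

  for (;;) {
    uvec rows(d);
    for (uword i = 0; i < d; ++i) rows(i) = idx[i];
    const mat A = P.rows(rows);
    vec nrm = hyperplane_normal(A);
    const double nn = norm(nrm);
    if (nn > ntol) {
      nrm /= nn;
      double off = dot(nrm, A.row(0).t());
      vec s = P * nrm - off * ones<vec>(m);
      const double smin = s.min(), smax = s.max();
      if (!(smin < -tol && smax > tol)) {  // supporting hyperplane
        if (smax > tol) { nrm = -nrm; off = -off; s = -s; }  // outward
        std::vector<long long> key(d + 1);
        for (uword j = 0; j < d; ++j)
          key[j] = llround(nrm(j) * 1e7);
        key[d] = llround(off / scale * 1e7);
        if (seen.insert(key).second) {
          const uvec on = find(s > -tol);  // all s <= tol already
          double base;
          if (on.n_elem == d) {
            base = facet_simplex_volume(P.rows(on));
          } else {
            // cohyperplanar facet: project into the flat and recurse
            const mat basis = null(nrm.t());  // d x (d-1)
            mat Q = P.rows(on);
            Q.each_row() -= P.row(on(0));
            base = hull_volume_rec(Q * basis);
          }
          const double height = std::abs(dot(cen.t(), nrm) - off);
          vol += base * height / static_cast<double>(d);
        }
      }
    }
    // next combination
    sword pos = d - 1;
    while (pos >= 0 && idx[pos] == m - d + pos) --pos;
    if (pos < 0) break;
    ++idx[pos];
    for (uword j = pos + 1; j < d; ++j) idx[j] = idx[j - 1] + 1;
  }
  return vol;
}

//' @keywords internal
// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(const arma::mat& pts) {
  return hull_volume_rec(pts);
}

// Supporting halfspaces (outward unit normals and offsets) of the hull,
// used by tests for point-membership cross-checks.
// [[Rcpp::export(name = ".hull_facets_cpp")]]
Rcpp::List hull_facets_cpp(const arma::mat& P) {
  const uword m = P.n_rows, d = P.n_cols;
  const double scale = std::max(1.0, abs(P).max());
  const double tol = 1e-9 * scale;
  const double ntol = 1e-10 * std::pow(scale, static_cast<double>(d - 1));

  std::vector<uword> idx(d);
  for (uword i = 0; i < d; ++i) idx[i] = i;
  std::set<std::vector<long long>> seen;
  std::vector<vec> normals;
  std::vector<double> offsets;

  if (m >= d) {
    for (;;) {
      uvec rows(d);
      for (uword i = 0; i < d; ++i) rows(i) = idx[i];
      const mat A = P.rows(rows);
      vec nrm = hyperplane_normal(A);
      const double nn = norm(nrm);
      if (nn > ntol) {
        nrm /= nn;
        double off = dot(nrm, A.row(0).t());
        vec s = P * nrm - off * ones<vec>(m);
        if (!(s.min() < -tol && s.max() > tol)) {
          if (s.max() > tol) { nrm = -nrm; off = -off; }
          std::vector<long long> key(d + 1);
          for (uword j = 0; j < d; ++j) key[j] = llround(nrm(j) * 1e7);
          key[d] = llround(off / scale * 1e7);
          if (seen.insert(key).second) {
            normals.push_back(nrm);
            offsets.push_back(off);
          }
        }
      }
      sword pos = d - 1;
      while (pos >= 0 && idx[pos] == m - d + pos) --pos;
      if (pos < 0) break;
      ++idx[pos];
      for (uword j = pos + 1; j < d; ++j) idx[j] = idx[j - 1] + 1;
    }
  }
  mat N(normals.size(), d);
  vec o(offsets.size());
  for (size_t i = 0; i < normals.size(); ++i) {
    N.row(i) = normals[i].t();
    o(i) = offsets[i];
  }
  return Rcpp::List::create(Rcpp::Named("normals") = N,
                            Rcpp::Named("offsets") = o);
}
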