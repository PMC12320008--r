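// Computational kernels: closed-form spherical-conductor dipole fields,
// least-squares residual for the nonlinear dipole fit, tensor-product
// cubic B-spline evaluation, and the LCMV scan loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double MU0_OVER_4PI = 1e-7;

// Field pickup of unit dipoles along x,y,z at source r0 (relative to the
// sphere center) on magnetometers at positions `pos` with orientations
// `ori` (both relative coordinates handled by caller subtracting center).
// Returns nchan x 3 block. Sarvas closed form.
static void sarvas_block(const mat& pos, const mat& ori, const rowvec& r0,
                         mat& out) {
  const uword n = pos.n_rows;
  for (uword c = 0; c < n; ++c) {
    rowvec r = pos.row(c);
    rowvec a = r - r0;
    double A = norm(a, 2);
    double R = norm(r, 2);
    double adotr = dot(a, r);
    double F = A * (R * A + R * R - dot(r0, r));
    rowvec gradF = (A * A / R + adotr / A + 2.0 * A + 2.0 * R) * r
                 - (A + 2.0 * R + adotr / A) * r0;
    // B(Q) = mu0/(4 pi F^2) * (F Q x r0 - (Q x r0 . r) gradF)
    // For unit Q = e_k, Q x r0 has rows cross(e_k, r0).
    mat qxr0(3, 3);
    // cross(e_x, r0) = (0, -r0z, r0y), etc.
    qxr0(0, 0) = 0.0;      qxr0(0, 1) = -r0(2);  qxr0(0, 2) = r0(1);
    qxr0(1, 0) = r0(2);    qxr0(1, 1) = 0.0;     qxr0(1, 2) = -r0(0);
    qxr0(2, 0) = -r0(1);   qxr0(2, 1) = r0(0);   qxr0(2, 2) = 0.0;
    double invF2 = MU0_OVER_4PI / (F * F);
    for (uword k = 0; k < 3; ++k) {
      rowvec v = qxr0.row(k);
      rowvec B = invF2 * (F * v - dot(v, r) * gradF);
      out(c, k) = dot(B, ori.row(c));
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_sarvas_leadfield(const arma::mat& sens_pos,
                               const arma::mat& sens_ori,
                               const arma::mat& sources,
                               const arma::rowvec& center) {
  const uword nchan = sens_pos.n_rows;
  const uword nsrc = sources.n_rows;
  mat pos = sens_pos.each_row() - center;
  mat L(nchan, 3 * nsrc);
  mat block(nchan, 3);
  for (uword s = 0; s < nsrc; ++s) {
    rowvec r0 = sources.row(s) - center;
    sarvas_block(pos, sens_ori, r0, block);
    L.cols(3 * s, 3 * s + 2) = block;
  }
  return L;
}

// Residual fraction ||d - L m||^2 / ||d||^2 with m the truncated-SVD
// least-squares moment at `source`. Returns 1 + penalty outside the head.
// [[Rcpp::export]]
double cpp_residual_fraction(const arma::rowvec& source,
                             const arma::vec& topo,
                             const arma::mat& sens_pos,
                             const arma::mat& sens_ori,
                             const arma::rowvec& center,
                             const arma::rowvec& head_center,
                             const arma::rowvec& head_semi) {
  rowvec q = (source - head_center) / head_semi;
  double ellval = dot(q, q);
  if (ellval >= 1.0) {
    // outside the head: penalty grows with distance from the surface
    double d = (std::sqrt(ellval) - 1.0) * head_semi.min();
    return 1.0 + d * 1e3;
  }
  rowvec r0 = source - center;
  if (norm(r0, 2) < 1e-9) return 1.0 + 1e-3;
  mat pos = sens_pos.each_row() - center;
  mat L(sens_pos.n_rows, 3);
  sarvas_block(pos, sens_ori, r0, L);
  mat U; vec s; mat V;
  if (!svd_econ(U, s, V, L)) return 1.0;
  double tol = s.max() * 1e-10;
  vec ut = U.t() * topo;
  vec fit = zeros<vec>(topo.n_elem);
  for (uword k = 0; k < s.n_elem; ++k) {
    if (s(k) > tol) fit += U.col(k) * ut(k);
  }
  double denom = dot(topo, topo);
  vec res = topo - fit;
  return dot(res, res) / denom;
}

// Nelder-Mead simplex minimization of the residual fraction over the
// dipole position. Initial simplex: 5 mm steps along each axis.
// Convergence: relative spread of the simplex function values.
// [[Rcpp::export]]
Rcpp::List cpp_fit_dipole(const arma::rowvec& start,
                          const arma::vec& topo,
                          const arma::mat& sens_pos,
                          const arma::mat& sens_ori,
                          const arma::rowvec& center,
                          const arma::rowvec& head_center,
                          const arma::rowvec& head_semi,
                          double reltol, int maxit) {
  const double alpha = 1.0, gammac = 2.0, rho = 0.5, sigma = 0.5;
  const double step = 5e-3;
  mat simplex(4, 3);
  vec fval(4);
  int nev = 0;
  auto f = [&](const rowvec& p) {
    ++nev;
    return cpp_residual_fraction(p, topo, sens_pos, sens_ori, center,
                                 head_center, head_semi);
  };
  simplex.row(0) = start;
  fval(0) = f(start);
  for (int i = 0; i < 3; ++i) {
    rowvec p = start;
    p(i) += step;
    simplex.row(i + 1) = p;
    fval(i + 1) = f(p);
  }
  bool converged = false;
  while (nev < maxit) {
    uvec ord = sort_index(fval);
    simplex = simplex.rows(ord);
    fval = fval(ord);
    if (std::abs(fval(3) - fval(0)) <=
        reltol * (std::abs(fval(0)) + reltol)) {
      converged = true;
      break;
    }
    rowvec centroid = mean(simplex.rows(0, 2), 0);
    rowvec xr = centroid + alpha * (centroid - simplex.row(3));
    double fr = f(xr);
    if (fr < fval(0)) {
      rowvec xe = centroid + gammac * (xr - centroid);
      double fe = f(xe);
      if (fe < fr) { simplex.row(3) = xe; fval(3) = fe; }
      else         { simplex.row(3) = xr; fval(3) = fr; }
    } else if (fr < fval(2)) {
      simplex.row(3) = xr; fval(3) = fr;
    } else {
      rowvec xc;
      if (fr < fval(3)) xc = centroid + rho * (xr - centroid);
      else xc = centroid - rho * (centroid - simplex.row(3));
      double fc = f(xc);
      if (fc < std::min(fr, fval(3))) {
        simplex.row(3) = xc; fval(3) = fc;
      } else {
        for (int i = 1; i < 4; ++i) {
          simplex.row(i) = simplex.row(0) +
            sigma * (simplex.row(i) - simplex.row(0));
          fval(i) = f(simplex.row(i));
        }
      }
    }
  }
  uvec ord = sort_index(fval);
  return Rcpp::List::create(
    Rcpp::Named("par") = simplex.row(ord(0)),
    Rcpp::Named("value") = fval(ord(0)),
    Rcpp::Named("fevals") = nev,
    Rcpp::Named("converged") = converged);
}

// --- tensor-product cubic B-spline evaluation -------------------------------
// Coefficient array `coef` has dims (nx+2, ny+2, nz+2), computed in R.
// Queries are clamped to the lattice box; the number of clamped queries is
// returned via attribute handled by the R wrapper.
static inline void bspl_weights(double u, double* w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  w[3] = u3 / 6.0;
}

// [[Rcpp::export]]
Rcpp::List cpp_bspline3_eval(const arma::cube& coef,
                             const arma::mat& query,
                             const arma::vec& x0, const arma::vec& h,
                             const arma::ivec& n) {
  const uword nq = query.n_rows;
  vec out(nq);
  int nclamp = 0;
  double wx[4], wy[4], wz[4];
  for (uword q = 0; q < nq; ++q) {
    double t[3];
    bool clamped = false;
    for (int d = 0; d < 3; ++d) {
      t[d] = (query(q, d) - x0(d)) / h(d);
      double tmax = (double)(n(d) - 1);
      // tolerance so lattice boundary nodes do not count as clamped
      if (t[d] < 0.0) { if (t[d] < -1e-9) clamped = true; t[d] = 0.0; }
      if (t[d] > tmax) { if (t[d] > tmax + 1e-9) clamped = true; t[d] = tmax; }
    }
    if (clamped) ++nclamp;
    int ix = std::min((int)std::floor(t[0]), (int)n(0) - 2);
    int iy = std::min((int)std::floor(t[1]), (int)n(1) - 2);
    int iz = std::min((int)std::floor(t[2]), (int)n(2) - 2);
    if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
    bspl_weights(t[0] - ix, wx);
    bspl_weights(t[1] - iy, wy);
    bspl_weights(t[2] - iz, wz);
    double acc = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        for (int c = 0; c < 4; ++c)
          acc += wx[a] * wy[b] * wz[c] * coef(ix + a, iy + b, iz + c);
    out(q) = acc;
  }
  return Rcpp::List::create(Rcpp::Named("values") = out,
                            Rcpp::Named("n_clamped") = nclamp);
}

// --- LCMV scan --------------------------------------------------------------
// For each 3-column leadfield block: restrict to the numerically non-silent
// orientation subspace, then report the maximum over orientations of the
// active-to-baseline output power ratio of the minimum-variance filter
// (a pseudo-F statistic; generalized eigenproblem of the two projected
// class second-moment matrices).
// [[Rcpp::export]]
arma::vec cpp_lcmv_scan(const arma::mat& Cinv,
                        const arma::mat& Ca,
                        const arma::mat& Cb,
                        const arma::mat& L) {
  const uword nsrc = L.n_cols / 3;
  mat X = Cinv * L;          // nchan x 3N
  mat Ya = Ca * X;
  mat Yb = Cb * X;
  vec out(nsrc);
  for (uword k = 0; k < nsrc; ++k) {
    mat Lk = L.cols(3 * k, 3 * k + 2);
    mat Xk = X.cols(3 * k, 3 * k + 2);
    mat A = symmatu(0.5 * (Lk.t() * Xk + Xk.t() * Lk));
    mat Wa = Xk.t() * Ya.cols(3 * k, 3 * k + 2);
    mat Wb = Xk.t() * Yb.cols(3 * k, 3 * k + 2);
    vec ev; mat EV;
    eig_sym(ev, EV, A);
    uvec keep = find(ev > ev.max() * 1e-8);
    mat P = EV.cols(keep);
    mat War = P.t() * Wa * P, Wbr = P.t() * Wb * P;
    mat M;
    bool ok = solve(M, Wbr, War);
    if (!ok) { M = pinv(Wbr) * War; }
    cx_vec eigval = eig_gen(M);
    out(k) = real(eigval).max();
  }
  return out;
}
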