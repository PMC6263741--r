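// Hot numerical kernels: complex-domain batch OMP, the ADMM l1 coder used by
// online dictionary learning, and overlapping-patch accumulation.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Batch orthogonal matching pursuit over the columns of X, with the Gram
// matrix G = D^H D precomputed once and an incremental Cholesky factor of
// G_QQ per patch, so each atom selection costs O(k |Q|) instead of O(k w^2).
// Stopping rule per column: squared residual <= delta or |Q| == max_atoms.
// Ties in the selection argmax break to the lowest atom index.
// [[Rcpp::export]]
Rcpp::List omp_batch(const arma::cx_mat& X, const arma::cx_mat& D,
                     const double delta, const int max_atoms) {
  const uword k = D.n_cols;
  const uword P = X.n_cols;
  const int L = std::min<int>(max_atoms, (int)k);

  cx_mat G = D.t() * D;          // k x k Gram (Hermitian)
  cx_mat C0 = D.t() * X;         // k x P initial correlations
  cx_mat recon(D.n_rows, P, fill::zeros);

  std::vector<unsigned int> all_idx;
  std::vector<std::complex<double>> all_coef;
  Rcpp::IntegerVector lens(P);
  Rcpp::NumericVector rnorm2(P);

  cx_mat Lmat(L, L);             // incremental Cholesky of G_QQ
  uvec Q(L);
  cx_vec c(k), c0(k), alpha;

  for (uword p = 0; p < P; ++p) {
    c0 = C0.col(p);
    c = c0;
    double eps = std::real(cdot(X.col(p), X.col(p)));
    int m = 0;
    while (eps > delta && m < L) {
      // argmax |c_j|, lowest index on ties
      vec ac = abs(c);
      uword jstar = 0; double best = -1.0;
      for (uword j = 0; j < k; ++j) {
        if (ac(j) > best + 1e-15) { best = ac(j); jstar = j; }
      }
      // skip already-selected atoms (their correlation is ~0 but guard anyway)
      bool dup = false;
      for (int t = 0; t < m; ++t) if (Q(t) == jstar) { dup = true; break; }
      if (dup) break;
      // extend the Cholesky factor of G_QQ with column jstar
      if (m == 0) {
        double gjj = std::real(G(jstar, jstar));
        if (gjj <= 0) break;
        Lmat(0, 0) = std::sqrt(gjj);
      } else {
        cx_vec g(m);
        for (int t = 0; t < m; ++t) g(t) = G(Q(t), jstar);
        cx_vec w = solve(trimatl(Lmat.submat(0, 0, m - 1, m - 1)), g);
        double d2 = std::real(G(jstar, jstar)) - std::real(cdot(w, w));
        if (d2 <= 1e-14) break;  // numerically dependent atom: stop
        // G_QQ = L L^H: the appended row is the conjugate of the solve
        for (int t = 0; t < m; ++t) Lmat(m, t) = std::conj(w(t));
        for (int t = 0; t < m; ++t) Lmat(t, m) = 0;
        Lmat(m, m) = std::sqrt(d2);
      }
      Q(m) = jstar;
      ++m;
      // least-squares coefficients on the active set: G_QQ alpha = c0_Q
      cx_vec rhs(m);
      for (int t = 0; t < m; ++t) rhs(t) = c0(Q(t));
      cx_vec tmp = solve(trimatl(Lmat.submat(0, 0, m - 1, m - 1)), rhs);
      alpha = solve(trimatu(Lmat.submat(0, 0, m - 1, m - 1).t()), tmp);
      // correlation and residual-energy updates
      cx_mat GQ(k, m);
      for (int t = 0; t < m; ++t) GQ.col(t) = G.col(Q(t));
      c = c0 - GQ * alpha;
      double proj = 0.0;
      for (int t = 0; t < m; ++t)
        proj += std::real(std::conj(alpha(t)) * c0(Q(t)));
      double eps_new = std::real(cdot(X.col(p), X.col(p))) - proj;
      if (eps_new < -1e-9) eps_new = 0;  // numerical guard
      if (eps_new > eps + 1e-12) break;  // must be non-increasing
      eps = std::max(eps_new, 0.0);
    }
    if (m > 0) {
      cx_mat DQ(D.n_rows, m);
      for (int t = 0; t < m; ++t) DQ.col(t) = D.col(Q(t));
      recon.col(p) = DQ * alpha;
      for (int t = 0; t < m; ++t) {
        all_idx.push_back((unsigned int)Q(t) + 1u);  // 1-based for R
        all_coef.push_back(alpha(t));
      }
    }
    lens[p] = m;
    rnorm2[p] = eps;
  }

  Rcpp::IntegerVector idx(all_idx.begin(), all_idx.end());
  Rcpp::ComplexVector coef(all_idx.size());
  for (size_t i = 0; i < all_coef.size(); ++i) {
    coef[i].r = all_coef[i].real();
    coef[i].i = all_coef[i].imag();
  }
  return Rcpp::List::create(Rcpp::Named("recon") = recon,
                            Rcpp::Named("idx") = idx,
                            Rcpp::Named("coef") = coef,
                            Rcpp::Named("lens") = lens,
                            Rcpp::Named("rnorm2") = rnorm2);
}

static inline void soft_complex_mat(const cx_mat& V, const double kappa,
                                    cx_mat& out) {
  out.set_size(V.n_rows, V.n_cols);
  for (uword j = 0; j < V.n_cols; ++j)
    for (uword i = 0; i < V.n_rows; ++i) {
      const double m = std::abs(V(i, j));
      out(i, j) = (m > kappa) ? V(i, j) * ((m - kappa) / m)
                              : std::complex<double>(0, 0);
    }
}

// l1 sparse coding of each column of X by variable splitting + augmented
// Lagrangian (ADMM):  min ||x - D w||^2 + lambda ||a||_1  s.t. a = w.
// The whole batch is iterated as one matrix recursion (the quadratic-step
// inverse (G + rho I)^{-1} is computed once), so each ADMM step is a single
// level-3 BLAS product. A column counts as converged once its code change
// drops below tol (relative); iterations stop when every column has.
// [[Rcpp::export]]
Rcpp::List sparsal_batch(const arma::cx_mat& X, const arma::cx_mat& D,
                         const double lambda, const int max_iter,
                         const double tol, const double rho) {
  const uword k = D.n_cols;
  const uword P = X.n_cols;
  cx_mat G = D.t() * D;
  G.diag() += rho;
  const cx_mat Minv = inv_sympd(G);
  const cx_mat C0 = D.t() * X;
  cx_mat A(k, P, fill::zeros), Dd(k, P, fill::zeros), W, Anew;
  Rcpp::LogicalVector converged(P, false);
  std::vector<bool> done(P, false);
  const double kappa = lambda / (2.0 * rho);

  for (int it = 0; it < max_iter; ++it) {
    W = Minv * (C0 + rho * (A - Dd));
    soft_complex_mat(W + Dd, kappa, Anew);
    Dd += W - Anew;
    bool all_done = true;
    for (uword p = 0; p < P; ++p) {
      if (done[p]) continue;
      const double change = norm(Anew.col(p) - A.col(p));
      if (change <= tol * std::max(1.0, norm(Anew.col(p)))) {
        done[p] = true;
        converged[p] = true;
      } else {
        all_done = false;
      }
    }
    A = Anew;
    if (all_done) break;
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = A,
                            Rcpp::Named("converged") = converged);
}

// sum_i R_i^H p_i : scatter-add patch columns back into the image plane.
// idx holds 1-based linear pixel indices, one column per patch.
// [[Rcpp::export]]
arma::cx_vec patch_accumulate(const arma::cx_mat& P, const arma::mat& idx,
                              const int n) {
  cx_vec out(n, fill::zeros);
  for (uword j = 0; j < P.n_cols; ++j)
    for (uword i = 0; i < P.n_rows; ++i)
      out((uword)idx(i, j) - 1) += P(i, j);
  return out;
}
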